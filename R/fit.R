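#' Control parameters for PNP fitting
#'
#' @param n_subsets total budget of minimal trial subsets examined by the
#'   exact-fit search (per fit, across all rounds). The search stops early at
#'   the first admitted candidate, so easy fits use only a handful of
#'   subsets.
#' @param n_rounds maximal number of guided search rounds; later rounds
#'   re-order the trials by trimmed-least-squares residuals and run only when
#'   the earlier ones find no exact-fit candidate.
#' @param max_candidates number of distinct exact-fit candidates kept for the
#'   final likelihood comparison.
#' @param exact_tol numerical exactness tolerance: a trial supports an
#'   exact-fit candidate when its absolute residual is at most `exact_tol`.
#'   Default `1e-8 * sd(response)`, i.e. numerically exact agreement. A
#'   candidate needs strictly more supporting trials than parameters to be
#'   admitted, so that hyperplanes that merely interpolate noise are never
#'   mistaken for precise structure.
#' @param precise_mult the precise classification band in units of `tau`:
#'   a trial is classified precise when its absolute residual is at most
#'   `precise_mult * tau` (default 5).
#' @param em_maxit,em_tol iteration cap and relative log-likelihood tolerance
#'   of the expectation-maximisation polish.
#' @param seed integer seed for the fit's internal randomness (subset draws);
#'   the user's RNG state is restored afterwards.
#' @param nonlinear_starts sensitivity (`delta`) start values for the
#'   multi-start search used with the exemplar algorithm.
#' @param optim_maxit iteration cap for the Nelder-Mead searches used with
#'   nonlinear algorithms.
#' @return A list of class `"pnp_control"`.
#' @export
pnp_control <- function(n_subsets = 2000L, n_rounds = 3L, max_candidates = 3L,
                        exact_tol = NULL, precise_mult = 5,
                        em_maxit = 300L, em_tol = 1e-10, seed = 1L,
                        nonlinear_starts = c(0.1, 1, 10),
                        optim_maxit = 500L) {
  out <- list(n_subsets = as.integer(n_subsets), n_rounds = as.integer(n_rounds),
              max_candidates = as.integer(max_candidates),
              exact_tol = exact_tol, precise_mult = precise_mult,
              em_maxit = as.integer(em_maxit), em_tol = em_tol,
              seed = as.integer(seed), nonlinear_starts = nonlinear_starts,
              optim_maxit = as.integer(optim_maxit))
  class(out) <- "pnp_control"
  out
}

#' Fit the precise/not-precise mixture model
#'
#' Fits, by maximum likelihood, the two-component mixture in which each
#' response is either a numerically exact execution of a reference algorithm
#' `g(x | theta)` (narrow Gaussian component, fixed sd `tau`) or an
#' error-perturbed execution (wide component, sd `sigma`), with mixture
#' probability `lambda` of a non-precise response. With `lambda = 1` the
#' model reduces to the conventional homogeneous Gaussian regression
#' `y = g(x | theta) + N(0, sigma^2)`, which serves as the baseline model.
#'
#' The likelihood surface has needle-like optima: when a subset of trials
#' matches some `theta` exactly, the narrow component rewards that `theta`
#' enormously, but smooth optimisers started from a least-squares solution
#' never find it. The fitter therefore combines (i) an exact-fit consensus
#' search — solving `g(x | theta) = y` on many minimal trial subsets, guided
#' towards small-residual trials, and keeping parameter candidates that are
#' matched exactly by more trials than they have parameters; (ii)
#' classification-based estimation (`lambda` = share of non-precise trials,
#' `sigma` from the non-precise residuals, `theta` from the precise trials);
#' (iii) an EM polish; and (iv) the `lambda = 1` Gaussian solution, always
#' included as a candidate. The candidate with the highest mixture
#' log-likelihood is returned, so the fitted log-likelihood never falls below
#' the Gaussian baseline's likelihood evaluated under the mixture density.
#'
#' @param formula model formula `response ~ cue_1 + ... + cue_k`; the
#'   right-hand-side variables are passed to the reference algorithm as its
#'   cue columns, in order.
#' @param data data frame containing the formula's variables.
#' @param algorithm a reference algorithm name or [pnp_algorithm()] object.
#' @param tau standard deviation of the precise component (a technical
#'   constant defining the tolerance band of a precise response, not an error
#'   estimate). Default `NULL` applies the convention `sd(response) * 1e-3`
#'   — three decimal orders below the variation of the response.
#' @param lambda `NULL` to estimate the mixture probability (the PNP model),
#'   or a fixed value; `lambda = 1` fits the homogeneous Gaussian baseline
#'   with the corresponding smaller free-parameter count.
#' @param control a [pnp_control()] list.
#' @return An object of class `"pnp"` with components `theta`, `lambda`,
#'   `sigma`, `tau`, `loglik`, `n`, `k_free`, `bic`, `adj_r2`, `precise`
#'   (per-trial posterior classification), `sigma_defined` (`FALSE` when no
#'   trial is classified non-precise, in which case `sigma` is `NA`:
#'   execution error is only measured on errors that actually occurred),
#'   `fitted.values`, `residuals` and bookkeeping fields. Methods:
#'   [print()], [summary()], [coef()], [logLik()], [predict()],
#'   [residuals()], [fitted()], [simulate()], [plot()].
#' @examples
#' set.seed(1)
#' d <- simulate_participant("linear_additive", theta = c(50, 4, 3, 2, 1),
#'                           lambda = 0.3, sigma = 10, n = 50, seed = 7)
#' fit <- pnp(response ~ cue_1 + cue_2 + cue_3 + cue_4, d)
#' coef(fit); fit$lambda
#' base <- pnp(response ~ cue_1 + cue_2 + cue_3 + cue_4, d, lambda = 1)
#' BIC(fit) < BIC(base)
#' @seealso [pnp_algorithm()], [select_model()], [run_recovery()]
#' @export
pnp <- function(formula, data, algorithm = "linear_additive", tau = NULL,
                lambda = NULL, control = pnp_control()) {
  cl <- match.call()
  mt <- stats::terms(formula, data = data)
  mf <- stats::model.frame(mt, data)
  y <- as.numeric(stats::model.response(mf))
  mm <- stats::model.matrix(mt, mf)
  C <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  fit <- .pnp_fit(y, C, algorithm, tau = tau, lambda = lambda,
                  control = control)
  fit$call <- cl
  fit$formula <- formula
  fit$terms <- mt
  fit
}

# core fitting routine on a response vector and cue matrix
.pnp_fit <- function(y, C, algorithm, tau = NULL, lambda = NULL,
                     control = pnp_control()) {
  C <- as.matrix(C)
  storage.mode(C) <- "double"
  if (!all(is.finite(y)) || !all(is.finite(C)))
    stop("responses and cues must be finite")
  n <- length(y)
  if (nrow(C) != n) stop("cue matrix and response lengths differ")
  algo <- .resolve_algorithm(algorithm, C)

  sd_y <- if (n > 1) stats::sd(y) else 0
  if (is.null(tau)) tau <- if (sd_y > 0) sd_y * 1e-3 else 1e-3
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive")

  fixed_lambda <- NULL
  if (!is.null(lambda)) {
    if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
      stop("fixed `lambda` must be a single value in [0, 1]")
    fixed_lambda <- as.numeric(lambda)
  }
  k_free <- algo$nfree + if (is.null(fixed_lambda)) 2L else 1L
  if (n < k_free)
    stop(sprintf("underdetermined fit: %d trial(s) for %d free parameter(s)",
                 n, k_free))

  sigma_min <- max(100 * tau, 1e-6 * sd_y, 1e-12)
  exact_tol <- control$exact_tol
  if (is.null(exact_tol)) exact_tol <- max(1e-8 * sd_y, 1e-12)
  precise_tol <- control$precise_mult * tau

  # restore the caller's RNG state; fits are deterministic given control$seed
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(control$seed)

  res <- if (isTRUE(algo$linear)) {
    .fit_linear(y, C, algo, tau, sigma_min, exact_tol, precise_tol,
                fixed_lambda, control)
  } else if (isTRUE(algo$fixed)) {
    .fit_fixedpred(y, C, algo, tau, sigma_min, precise_tol, fixed_lambda,
                   control)
  } else {
    .fit_nonlinear(y, C, algo, tau, sigma_min, precise_tol, fixed_lambda,
                   control)
  }

  if (sd_y == 0 && stats::var(res$fitted) > 0)
    warning("degenerate fit: constant responses with non-constant predictions")

  gaussian_model <- identical(fixed_lambda, 1)
  adj <- if (n >= algo$nfree + 2 && sd_y > 0)
    adjusted_r2(y, res$fitted, algo$nfree) else NA_real_
  theta <- res$theta
  if (length(theta)) names(theta) <- algo$param_names
  out <- list(
    theta = theta, lambda = res$lambda, sigma = res$sigma, tau = tau,
    loglik = res$loglik, n = n, k_free = k_free,
    bic = bic(res$loglik, k_free, n), adj_r2 = adj,
    precise = res$precise, sigma_defined = res$sigma_defined,
    fitted.values = res$fitted, residuals = y - res$fitted,
    y = y, cues = C, algorithm = algo,
    model = if (gaussian_model) "gaussian" else "pnp",
    degenerate = isTRUE(res$degenerate), fixed_lambda = fixed_lambda,
    sigma_min = sigma_min, control = control, info = res$info)
  class(out) <- "pnp"
  out
}

## ---- linear algorithms -----------------------------------------------------

.fit_linear <- function(y, C, algo, tau, sigma_min, exact_tol, precise_tol,
                        fixed_lambda, control) {
  F <- algo$features(C)
  n <- length(y); d <- ncol(F)
  ls <- stats::lm.fit(F, y)
  th_ols <- ls$coefficients
  th_ols[is.na(th_ols)] <- 0
  e_ols <- y - drop(F %*% th_ols)
  rss <- sum(e_ols^2)

  if (identical(fixed_lambda, 1)) {
    # homogeneous Gaussian baseline: ML theta coincides with least squares
    if (.degenerate_rss(rss, n, y)) {
      warning("degenerate Gaussian fit: zero residual variance")
      return(list(theta = th_ols, lambda = 1, sigma = 0, loglik = Inf,
                  precise = rep(FALSE, n), sigma_defined = FALSE,
                  fitted = drop(F %*% th_ols), degenerate = TRUE,
                  info = list(source = "least-squares")))
    }
    sig <- sqrt(rss / n)
    return(list(theta = th_ols, lambda = 1, sigma = sig,
                loglik = sum(stats::dnorm(e_ols, 0, sig, log = TRUE)),
                precise = rep(FALSE, n), sigma_defined = TRUE,
                fitted = drop(F %*% th_ols), degenerate = FALSE,
                info = list(source = "least-squares")))
  }

  cands <- list(list(theta = th_ols, source = "gaussian"))
  if (n >= d + 1) {
    for (th in .ransac(F, y, exact_tol, control))
      cands[[length(cands) + 1L]] <- list(theta = th, source = "exact-fit")
  }
  evals <- lapply(cands, function(cand)
    .eval_candidate(F, y, cand$theta, tau, sigma_min, precise_tol,
                    fixed_lambda, control, source = cand$source))
  if (is.null(fixed_lambda)) {
    # the lambda = 1 Gaussian solution is always in the comparison set
    evals[[length(evals) + 1L]] <-
      .finish_candidate(F, y, th_ols, 1, max(sqrt(rss / n), sigma_min),
                        tau, sigma_min, source = "gaussian")
  }
  best <- evals[[1L]]
  for (ev in evals[-1L]) if (ev$loglik > best$loglik + 1e-9) best <- ev
  best$info <- list(source = best$source,
                    candidates = length(evals),
                    exact_fit_candidates = length(evals) - 1L)
  best$fitted <- drop(F %*% best$theta)
  best$degenerate <- FALSE
  best
}

# evaluate one theta candidate: classification-based start, EM polish, and
# (for separated solutions) an exact classification refit; returns the best
.eval_candidate <- function(F, y, theta, tau, sigma_min, precise_tol,
                            fixed_lambda, control, source = "") {
  n <- length(y); d <- ncol(F)
  e <- y - drop(F %*% theta)
  pm <- abs(e) <= precise_tol
  m_np <- sum(!pm)
  if (m_np == 0 && is.null(fixed_lambda))
    return(.finish_candidate(F, y, theta, 0, NA_real_, tau, sigma_min,
                             source = source))
  lam0 <- if (!is.null(fixed_lambda)) fixed_lambda else m_np / n
  sig0 <- if (m_np > 0) max(sqrt(mean(e[!pm]^2)), sigma_min)
          else max(sqrt(mean(e^2)), sigma_min)
  em <- .pnp_em(F, y, theta, lam0, sig0, tau, sigma_min, fixed_lambda,
                control$em_maxit, control$em_tol)
  out <- .finish_candidate(F, y, em$theta, em$lambda, em$sigma, tau,
                           sigma_min, source = source, iter = em$iter)

  # exact refit: least squares on the posterior-precise set recovers the
  # needle theta to machine precision and lambda as a trial fraction
  if (is.null(fixed_lambda) && out$lambda > 0 && out$lambda < 1) {
    prec <- out$precise
    if (sum(prec) >= d && sum(prec) < n) {
      th_r <- stats::lm.fit(F[prec, , drop = FALSE], y[prec])$coefficients
      th_r[is.na(th_r)] <- 0
      e_r <- y - drop(F %*% th_r)
      np_r <- abs(e_r) > precise_tol
      lam_r <- mean(np_r)
      sig_r <- if (any(np_r)) max(sqrt(mean(e_r[np_r]^2)), sigma_min)
               else NA_real_
      ref <- .finish_candidate(F, y, th_r, lam_r, sig_r, tau, sigma_min,
                               source = source, iter = out$iter)
      if (ref$loglik >= out$loglik) out <- ref
    }
  }
  out
}

.finish_candidate <- function(F, y, theta, lambda, sigma, tau, sigma_min,
                              source = "", iter = 0L) {
  e <- y - drop(F %*% theta)
  lambda <- min(max(lambda, 0), 1)
  if (lambda == 0) {
    ll <- sum(stats::dnorm(e, 0, tau, log = TRUE))
    return(list(theta = theta, lambda = 0, sigma = NA_real_, loglik = ll,
                precise = rep(TRUE, length(y)), sigma_defined = FALSE,
                source = source, iter = iter))
  }
  ll <- sum(.pnp_ll_vec(e, lambda, sigma, tau))
  precise <- .posterior_precise(e, lambda, sigma, tau)
  list(theta = theta, lambda = lambda, sigma = sigma, loglik = ll,
       precise = precise, sigma_defined = any(!precise) && lambda > 0,
       source = source, iter = iter)
}

.posterior_precise <- function(e, lambda, sigma, tau) {
  if (lambda >= 1) return(rep(FALSE, length(e)))
  if (lambda <= 0) return(rep(TRUE, length(e)))
  la <- log(lambda) + stats::dnorm(e, 0, sigma, log = TRUE)
  lb <- log1p(-lambda) + stats::dnorm(e, 0, tau, log = TRUE)
  lb > la
}

# EM for the two-component mixture with shared mean surface; theta has a
# closed-form weighted-least-squares M-step for linear algorithms
.pnp_em <- function(F, y, theta, lam, sig, tau, sigma_min, fixed_lambda,
                    maxit, tol) {
  n <- length(y)
  update_theta <- !is.null(F) && ncol(F) > 0
  # with no mean parameters the caller passes the residual vector as y
  e <- if (update_theta) y - drop(F %*% theta) else y
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    if (lam <= 1e-10 && is.null(fixed_lambda)) { lam <- 0; break }
    if (lam >= 1) {
      r <- rep(1, n)
      ll <- sum(stats::dnorm(e, 0, sig, log = TRUE))
    } else if (lam <= 0) {
      r <- rep(0, n)
      ll <- sum(stats::dnorm(e, 0, tau, log = TRUE))
    } else {
      la <- log(lam) + stats::dnorm(e, 0, sig, log = TRUE)
      lb <- log1p(-lam) + stats::dnorm(e, 0, tau, log = TRUE)
      m <- pmax(la, lb)
      ll_i <- m + log(exp(la - m) + exp(lb - m))
      ll <- sum(ll_i)
      r <- exp(la - ll_i)
    }
    lam_new <- if (!is.null(fixed_lambda)) fixed_lambda else mean(r)
    sr <- sum(r)
    if (sr < 1e-10) {
      if (is.null(fixed_lambda)) { lam <- 0; break }
      sig_new <- sig
    } else {
      sig_new <- max(sqrt(sum(r * e^2) / sr), sigma_min)
    }
    if (update_theta) {
      w <- r / sig_new^2 + (1 - r) / tau^2
      A <- crossprod(F, F * w)
      b <- crossprod(F, y * w)
      th_new <- tryCatch(drop(solve(A, b)), error = function(err) theta)
      theta <- th_new
      e <- y - drop(F %*% theta)
    }
    lam <- min(max(lam_new, 0), 1)
    sig <- sig_new
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    if (it >= maxit) break
  }
  if (lam <= 1e-10 && is.null(fixed_lambda)) { lam <- 0; sig <- NA_real_ }
  list(theta = theta, lambda = lam, sigma = sig, iter = it)
}

# a residual sum of squares at numerical-noise scale means the data sit
# exactly on the fitted surface: sigma-hat is reported as 0 and flagged
.degenerate_rss <- function(rss, n, y) {
  sd_y <- if (length(y) > 1) stats::sd(y) else 0
  rss == 0 || sqrt(rss / n) <= 1e-10 * sd_y
}

## ---- exact-fit consensus search -------------------------------------------

# guided random-subset search for parameter vectors matched exactly by more
# trials than they have parameters; returns a list of candidate thetas.
# Subsets are drawn from pools of trials with the smallest reference
# residuals (several pool sizes, exhaustively for tiny pools); the search
# stops at the first admitted candidate, because consolidating on its full
# exact-support set already recovers every precise trial. If a full round
# finds nothing, the trials are re-ordered by the residuals of successively
# harder-trimmed least-squares refits and the search repeats.
.ransac <- function(F, y, exact_tol, control) {
  n <- length(y); d <- ncol(F)
  if (n < d + 1) return(list())
  th0 <- stats::lm.fit(F, y)$coefficients
  th0[is.na(th0)] <- 0
  e_ref <- y - drop(F %*% th0)

  found <- list()   # key -> list(theta, count)
  consider <- function(th) {
    if (is.null(th) || !all(is.finite(th))) return(invisible(NULL))
    inl <- which(abs(y - drop(F %*% th)) <= exact_tol)
    if (length(inl) < d + 1) return(invisible(NULL))
    # consolidate on the full support set
    th2 <- stats::lm.fit(F[inl, , drop = FALSE], y[inl])$coefficients
    th2[is.na(th2)] <- 0
    inl2 <- which(abs(y - drop(F %*% th2)) <= exact_tol)
    if (length(inl2) < d + 1) { th2 <- th; inl2 <- inl }
    key <- paste(inl2, collapse = ",")
    if (is.null(found[[key]]))
      found[[key]] <<- list(theta = th2, count = length(inl2))
    invisible(NULL)
  }
  solve_subset <- function(idx) {
    consider(tryCatch(solve(F[idx, , drop = FALSE], y[idx]),
                      error = function(err) NULL))
  }

  n_rounds <- max(1L, control$n_rounds)
  trim <- c(0.6, 0.35)
  for (round in seq_len(n_rounds)) {
    ord <- order(abs(e_ref))
    pools <- unique(pmin(n, c(d + 2L, 2L * d + 1L, 3L * d + 2L,
                              ceiling(n / 2), n)))
    pools <- pools[pools > d]
    per <- max(1L, ceiling(control$n_subsets / (n_rounds * length(pools))))
    solve_subset(ord[seq_len(d)])
    for (q in pools) {
      if (length(found)) break
      if (choose(q, d) <= per) {
        sub <- utils::combn(q, d)
        for (s in seq_len(ncol(sub))) solve_subset(ord[sub[, s]])
      } else {
        for (s in seq_len(per)) solve_subset(ord[sample.int(q, d)])
      }
    }
    if (length(found) || round == n_rounds) break
    # no candidate: re-order by residuals from a trimmed refit and try again
    h <- max(d + 2L, ceiling(trim[min(round, length(trim))] * n))
    idx <- ord[seq_len(min(h, n))]
    th_t <- stats::lm.fit(F[idx, , drop = FALSE], y[idx])$coefficients
    th_t[is.na(th_t)] <- 0
    e_ref <- y - drop(F %*% th_t)
  }
  if (!length(found)) return(list())
  counts <- vapply(found, `[[`, numeric(1), "count")
  keep <- order(counts, decreasing = TRUE)[
    seq_len(min(control$max_candidates, length(found)))]
  lapply(found[keep], `[[`, "theta")
}

## ---- algorithms without free mean parameters ------------------------------

.fit_fixedpred <- function(y, C, algo, tau, sigma_min, precise_tol,
                           fixed_lambda, control) {
  pred <- algo$predict_fn(C, numeric(0))
  e <- y - pred
  n <- length(y)
  if (identical(fixed_lambda, 1)) {
    rss <- sum(e^2)
    if (.degenerate_rss(rss, n, y)) {
      warning("degenerate Gaussian fit: zero residual variance")
      return(list(theta = numeric(0), lambda = 1, sigma = 0, loglik = Inf,
                  precise = rep(FALSE, n), sigma_defined = FALSE,
                  fitted = pred, degenerate = TRUE,
                  info = list(source = "fixed-prediction")))
    }
    sig <- sqrt(rss / n)
    return(list(theta = numeric(0), lambda = 1, sigma = sig,
                loglik = sum(stats::dnorm(e, 0, sig, log = TRUE)),
                precise = rep(FALSE, n), sigma_defined = TRUE,
                fitted = pred, degenerate = FALSE,
                info = list(source = "fixed-prediction")))
  }
  best <- .eval_lamsig(e, tau, sigma_min, precise_tol, fixed_lambda, control)
  best$theta <- numeric(0)
  best$fitted <- pred
  best$degenerate <- FALSE
  best$info <- list(source = "fixed-prediction")
  best
}

# mixture fit of (lambda, sigma) for a fixed residual vector
.eval_lamsig <- function(e, tau, sigma_min, precise_tol, fixed_lambda,
                         control) {
  n <- length(e)
  pm <- abs(e) <= precise_tol
  m_np <- sum(!pm)
  cands <- list()
  if (m_np == 0 && is.null(fixed_lambda)) {
    return(list(lambda = 0, sigma = NA_real_,
                loglik = sum(stats::dnorm(e, 0, tau, log = TRUE)),
                precise = rep(TRUE, n), sigma_defined = FALSE))
  }
  if (m_np > 0 && m_np < n)
    cands[[length(cands) + 1L]] <-
      c(lam = if (is.null(fixed_lambda)) m_np / n else fixed_lambda,
        sig = max(sqrt(mean(e[!pm]^2)), sigma_min))
  cands[[length(cands) + 1L]] <-
    c(lam = if (is.null(fixed_lambda)) 1 else fixed_lambda,
      sig = max(sqrt(mean(e^2)), sigma_min))
  best <- NULL
  for (cand in cands) {
    em <- .pnp_em(NULL, e, numeric(0), cand[["lam"]], cand[["sig"]], tau,
                  sigma_min, fixed_lambda, control$em_maxit, control$em_tol)
    fin <- if (em$lambda == 0) {
      list(lambda = 0, sigma = NA_real_,
           loglik = sum(stats::dnorm(e, 0, tau, log = TRUE)),
           precise = rep(TRUE, n), sigma_defined = FALSE)
    } else {
      ll <- sum(.pnp_ll_vec(e, em$lambda, em$sigma, tau))
      prec <- .posterior_precise(e, em$lambda, em$sigma, tau)
      list(lambda = em$lambda, sigma = em$sigma, loglik = ll,
           precise = prec, sigma_defined = any(!prec) && em$lambda > 0)
    }
    if (is.null(best) || fin$loglik > best$loglik + 1e-9) best <- fin
  }
  best
}

## ---- nonlinear algorithms (exemplar) --------------------------------------

# unconstrained parametrisation: log(delta) plus k-1 attention logits
.exemplar_untransform <- function(p, k) {
  delta <- exp(p[1L])
  z <- c(p[-1L], 0)
  w <- exp(z - max(z))
  c(delta, w / sum(w))
}

.fit_nonlinear <- function(y, C, algo, tau, sigma_min, precise_tol,
                           fixed_lambda, control) {
  k <- algo$ncue
  n <- length(y)
  predfun <- function(p)
    .algo_predict(algo, C, .exemplar_untransform(p, k))
  starts <- lapply(control$nonlinear_starts,
                   function(dl) c(log(dl), rep(0, k - 1L)))

  # Gaussian stage: ML theta minimises the residual sum of squares
  rssfun <- function(p) sum((y - predfun(p))^2)
  gfit <- NULL
  for (p0 in starts) {
    op <- stats::optim(p0, rssfun, method = "Nelder-Mead",
                       control = list(maxit = control$optim_maxit))
    if (is.null(gfit) || op$value < gfit$value) gfit <- op
  }
  p_g <- gfit$par
  theta_g <- .exemplar_untransform(p_g, k)
  pred_g <- predfun(p_g)
  e_g <- y - pred_g
  rss <- sum(e_g^2)
  if (identical(fixed_lambda, 1)) {
    if (.degenerate_rss(rss, n, y)) {
      warning("degenerate Gaussian fit: zero residual variance")
      return(list(theta = theta_g, lambda = 1, sigma = 0, loglik = Inf,
                  precise = rep(FALSE, n), sigma_defined = FALSE,
                  fitted = pred_g, degenerate = TRUE,
                  info = list(source = "nonlinear-optim")))
    }
    sig <- sqrt(rss / n)
    return(list(theta = theta_g, lambda = 1, sigma = sig,
                loglik = sum(stats::dnorm(e_g, 0, sig, log = TRUE)),
                precise = rep(FALSE, n), sigma_defined = TRUE,
                fitted = pred_g, degenerate = FALSE,
                info = list(source = "nonlinear-optim")))
  }

  # mixture stage: profile likelihood over theta with (lambda, sigma)
  # maximised by EM for each residual vector
  profile <- function(p) {
    e <- y - predfun(p)
    -.eval_lamsig(e, tau, sigma_min, precise_tol, fixed_lambda,
                  control)$loglik
  }
  pfit <- NULL
  for (p0 in c(list(p_g), starts)) {
    op <- stats::optim(p0, profile, method = "Nelder-Mead",
                       control = list(maxit = control$optim_maxit))
    if (is.null(pfit) || op$value < pfit$value) pfit <- op
  }
  p_b <- pfit$par
  theta_b <- .exemplar_untransform(p_b, k)
  pred_b <- predfun(p_b)
  best <- .eval_lamsig(y - pred_b, tau, sigma_min, precise_tol, fixed_lambda,
                       control)
  best$theta <- theta_b
  best$fitted <- pred_b
  best$degenerate <- FALSE
  best$info <- list(source = "nonlinear-optim")
  best
}
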