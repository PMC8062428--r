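#' Simulate one participant's judgment data
#'
#' Generates trials from the precise/not-precise generative process: cue
#' vectors are drawn uniformly, each trial is perturbed with probability
#' `lambda` by Gaussian execution error `N(0, sigma^2)`, and is otherwise an
#' exact execution of the reference algorithm.
#'
#' @param algorithm reference algorithm name or [pnp_algorithm()] object.
#' @param theta true parameter vector of the algorithm.
#' @param lambda true probability of a non-precise response, in `[0, 1]`.
#' @param sigma true execution-error standard deviation.
#' @param n number of trials.
#' @param cue_min,cue_max bounds of the uniform cue distribution; scalars or
#'   one value per cue.
#' @param ncue number of cues; inferred from `theta` for `linear_additive`
#'   and from the algorithm otherwise.
#' @param participant participant id stored in the output.
#' @param repetition repetition index stored in the output.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A data frame with columns `participant_id`, `item_id`,
#'   `repetition`, `cue_1..cue_k` and `response`, plus attributes `precise`
#'   (logical: `TRUE` where the response is an exact execution) and `params`
#'   (the generating parameters).
#' @examples
#' d <- simulate_participant("linear_additive", c(50, 4, 3, 2, 1),
#'                           lambda = 0, sigma = 10, n = 5, seed = 1)
#' all(d$response == predict(pnp_algorithm("linear_additive", 4),
#'                           d[, paste0("cue_", 1:4)], c(50, 4, 3, 2, 1)))
#' @seealso [run_recovery()], [make_fixture()]
#' @export
simulate_participant <- function(algorithm, theta, lambda, sigma, n = 50,
                                 cue_min = 0, cue_max = 10, ncue = NULL,
                                 participant = 1L, repetition = 1L,
                                 seed = NULL) {
  if (lambda < 0 || lambda > 1) stop("`lambda` must be in [0, 1]")
  if (lambda > 0 && (!is.finite(sigma) || sigma <= 0))
    stop("`sigma` must be positive when lambda > 0")
  if (is.null(ncue)) {
    if (is.character(algorithm) && algorithm == "linear_additive") {
      ncue <- length(theta) - 1L
    } else if (inherits(algorithm, "pnp_algorithm")) {
      ncue <- algorithm$ncue
    } else {
      ncue <- pnp_algorithm(algorithm)$ncue
    }
  }
  if (is.na(ncue) || ncue < 1) stop("could not infer the number of cues")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  lo <- rep_len(cue_min, ncue)
  hi <- rep_len(cue_max, ncue)
  C <- vapply(seq_len(ncue), function(j) stats::runif(n, lo[j], hi[j]),
              numeric(n))
  C <- matrix(C, nrow = n)
  colnames(C) <- paste0("cue_", seq_len(ncue))
  algo <- .resolve_algorithm(algorithm, C)
  g <- .algo_predict(algo, C, as.numeric(theta))
  b <- stats::rbinom(n, 1L, lambda) == 1L
  response <- g
  if (any(b)) response[b] <- g[b] + stats::rnorm(sum(b), 0, sigma)
  out <- data.frame(participant_id = participant, item_id = seq_len(n),
                    repetition = repetition, C, response = response)
  attr(out, "precise") <- !b
  attr(out, "params") <- list(algorithm = algo$name, theta = theta,
                              lambda = lambda, sigma = sigma,
                              cue_min = lo, cue_max = hi)
  out
}

#' Per-participant seed scheme
#'
#' Deterministic counter scheme mapping a master seed and a participant
#' counter to that participant's generator seed, so any single simulated
#' participant can be re-generated in isolation:
#' `(master * 20011 + index * 7919) mod (2^31 - 1)`, shifted into `[1, 2^31)`.
#'
#' @param master master integer seed.
#' @param index 1-based participant counter.
#' @return An integer seed.
#' @export
participant_seed <- function(master, index) {
  r <- ((as.numeric(master) %% 2147483647) * 20011 +
          as.numeric(index) * 7919) %% 2147483647
  as.integer(r) + 1L
}

#' Per-parameter mean squared error
#'
#' @param estimates numeric matrix or data frame of estimates, one row per
#'   fit and one column per parameter.
#' @param truth numeric vector of generating values, one per column.
#' @return Named vector of `mean((estimate - truth)^2)` per parameter.
#' @export
parameter_mse <- function(estimates, truth) {
  E <- as.matrix(estimates)
  if (nrow(E) < 1) stop("`estimates` must be nonempty")
  if (ncol(E) != length(truth))
    stop("`truth` must have one value per column of `estimates`")
  out <- colMeans(sweep(E, 2L, as.numeric(truth))^2)
  names(out) <- colnames(E)
  out
}

#' Parameter-recovery study: PNP mixture versus Gaussian regression
#'
#' Simulates judgment data over a grid of error probabilities and, for every
#' simulated participant, fits both the precise/not-precise mixture and the
#' conventional Gaussian regression with the correct model structure (a
#' linear-additive rule by default) but unknown parameter values. Reports
#' per-grid-point means and mean squared errors of all parameter estimates,
#' grand means across the grid, and the overall mean squared error of the
#' mixture's error-probability estimate.
#'
#' The default design is a desk-scale version of the full study (a 21-point
#' grid with 100 participants per point, rather than 101 points with 1,000
#' participants each); pass `lambda_grid = seq(0, 1, by = 0.01)` and
#' `n_participants = 1000` for the full design.
#'
#' @param lambda_grid ordered vector of generating error probabilities in
#'   `[0, 1]`.
#' @param n_participants simulated participants per grid point.
#' @param n_trials trials per participant.
#' @param theta generating algorithm parameters.
#' @param sigma generating execution-error standard deviation.
#' @param cue_min,cue_max uniform cue bounds.
#' @param algorithm reference algorithm (default the linear-additive rule).
#' @param tau fixed precise-component sd passed to the fits; default `NULL`
#'   applies each participant's `sd(response) * 1e-3`.
#' @param seed master seed; per-participant seeds follow
#'   [participant_seed()].
#' @param control a [pnp_control()] list used for every mixture fit.
#' @param progress print one progress line per grid point.
#' @return An object of class `"pnp_recovery"`: a list with `estimates` (one
#'   row per participant and model), `per_lambda` (tidy: one row per grid
#'   point, model and parameter, with the mean estimate and its MSE),
#'   `grand` (grand means across grid points; the mixture's sigma summaries
#'   use only fits in which errors actually occurred), `lambda_mse` (mean
#'   squared error of the mixture's lambda estimates over all fits),
#'   `n_failed`, and the configuration.
#' @seealso [simulate_participant()], [pnp()]
#' @export
run_recovery <- function(lambda_grid = seq(0, 1, by = 0.05),
                         n_participants = 100, n_trials = 50,
                         theta = c(50, 4, 3, 2, 1), sigma = 10,
                         cue_min = 0, cue_max = 10,
                         algorithm = "linear_additive", tau = NULL,
                         seed = 1L, control = pnp_control(),
                         progress = FALSE) {
  lambda_grid <- as.numeric(lambda_grid)
  if (anyDuplicated(lambda_grid) || any(lambda_grid < 0 | lambda_grid > 1))
    stop("`lambda_grid` values must be unique and in [0, 1]")
  if (n_participants < 1 || n_trials < 1)
    stop("`n_participants` and `n_trials` must be at least 1")
  ncue <- if (is.character(algorithm) && algorithm == "linear_additive")
    length(theta) - 1L else NULL

  pn <- if (is.character(algorithm) && algorithm == "linear_additive")
    c("alpha", paste0("beta_", seq_len(ncue)))
  else pnp_algorithm(algorithm)$param_names
  rows <- vector("list", 2L * length(lambda_grid) * n_participants)
  n_failed <- 0L
  idx <- 0L
  for (li in seq_along(lambda_grid)) {
    lam <- lambda_grid[li]
    for (p in seq_len(n_participants)) {
      idx <- idx + 1L
      sd_p <- participant_seed(seed, idx)
      dat <- simulate_participant(algorithm, theta, lam, sigma,
                                  n = n_trials, cue_min = cue_min,
                                  cue_max = cue_max, ncue = ncue,
                                  participant = p, seed = sd_p)
      C <- as.matrix(dat[, grep("^cue_", names(dat)), drop = FALSE])
      y <- dat$response
      for (model in c("pnp", "reg")) {
        fit <- tryCatch(
          .pnp_fit(y, C, algorithm, tau = tau,
                   lambda = if (model == "reg") 1 else NULL,
                   control = control),
          error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fit)) {
          # refit, tolerating warnings (e.g. degenerate zero-variance fits)
          fit <- tryCatch(suppressWarnings(
            .pnp_fit(y, C, algorithm, tau = tau,
                     lambda = if (model == "reg") 1 else NULL,
                     control = control)), error = function(e) NULL)
        }
        if (is.null(fit)) {
          n_failed <- n_failed + 1L
          next
        }
        th <- as.list(fit$theta)
        names(th) <- pn
        rows[[2L * (idx - 1L) + match(model, c("pnp", "reg"))]] <-
          c(list(lambda_true = lam, participant = p, seed = sd_p,
                 model = model), th,
            list(sigma = if (fit$model == "gaussian" || fit$sigma_defined)
                   fit$sigma else NA_real_,
                 lambda_hat = fit$lambda,
                 sigma_defined = fit$sigma_defined))
      }
    }
    if (progress)
      message(sprintf("lambda = %.2f done (%d/%d grid points)",
                      lam, li, length(lambda_grid)))
  }
  est <- do.call(rbind, lapply(rows[!vapply(rows, is.null, logical(1))],
                               function(r) as.data.frame(r)))
  truth <- c(as.numeric(theta), sigma)
  names(truth) <- c(pn, "sigma")

  per <- list()
  for (lam in lambda_grid) {
    for (model in c("pnp", "reg")) {
      sub <- est[est$lambda_true == lam & est$model == model, , drop = FALSE]
      if (!nrow(sub)) next
      for (par in c(pn, "sigma", if (model == "pnp") "lambda")) {
        if (par == "lambda") {
          v <- sub$lambda_hat
          tr <- lam
        } else if (par == "sigma") {
          v <- if (model == "pnp") sub$sigma[sub$sigma_defined] else sub$sigma
          tr <- sigma
        } else {
          v <- sub[[par]]
          tr <- truth[[par]]
        }
        per[[length(per) + 1L]] <- data.frame(
          lambda = lam, model = model, parameter = par,
          n_fits = sum(!is.na(v)),
          mean = if (length(v) && any(!is.na(v))) mean(v, na.rm = TRUE)
                 else NA_real_,
          mse = if (length(v) && any(!is.na(v)))
                  mean((v - tr)^2, na.rm = TRUE) else NA_real_)
      }
    }
  }
  per_lambda <- do.call(rbind, per)

  grand <- do.call(rbind, lapply(c("pnp", "reg"), function(model) {
    sub <- per_lambda[per_lambda$model == model &
                        per_lambda$parameter != "lambda", , drop = FALSE]
    stats::aggregate(mean ~ parameter, data = sub[!is.na(sub$mean), ],
                     FUN = mean) |>
      transform(model = model)
  }))
  grand <- grand[, c("model", "parameter", "mean")]

  pnp_est <- est[est$model == "pnp", , drop = FALSE]
  lambda_mse <- mean((pnp_est$lambda_hat - pnp_est$lambda_true)^2)

  out <- list(estimates = est, per_lambda = per_lambda, grand = grand,
              lambda_mse = lambda_mse, n_failed = n_failed,
              config = list(lambda_grid = lambda_grid,
                            n_participants = n_participants,
                            n_trials = n_trials, theta = theta,
                            sigma = sigma, cue_min = cue_min,
                            cue_max = cue_max, algorithm = algorithm,
                            tau = tau, seed = seed))
  class(out) <- "pnp_recovery"
  out
}

#' @export
print.pnp_recovery <- function(x, digits = 3, ...) {
  cfg <- x$config
  cat(sprintf(
    "Parameter recovery: %d lambda points x %d participants x %d trials\n",
    length(cfg$lambda_grid), cfg$n_participants, cfg$n_trials))
  cat("Grand means of parameter estimates across the grid:\n")
  g <- x$grand
  wide <- stats::reshape(g, idvar = "model", timevar = "parameter",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  print(cbind(wide["model"], round(wide[-1], digits)), row.names = FALSE)
  cat(sprintf("Mixture lambda MSE over all fits: %.5f\n", x$lambda_mse))
  if (x$n_failed) cat(sprintf("Failed fits: %d\n", x$n_failed))
  invisible(x)
}
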