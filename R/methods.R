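#' @export
print.pnp <- function(x, digits = 3, ...) {
  cat(sprintf("%s fit (algorithm: %s, n = %d trials)\n",
              if (x$model == "pnp") "Precise/not-precise mixture"
              else "Homogeneous Gaussian", x$algorithm$name, x$n))
  if (length(x$theta)) {
    cat("  theta:\n")
    print(round(x$theta, digits))
  } else {
    cat("  theta: none (fixed reference function)\n")
  }
  cat(sprintf("  lambda = %s   sigma = %s   tau = %.3g\n",
              format(round(x$lambda, digits)),
              if (x$sigma_defined) format(round(x$sigma, digits))
              else "undefined (no errors occurred)",
              x$tau))
  cat(sprintf("  logLik = %.*f   BIC = %.*f   adj. R^2 = %s\n",
              digits, x$loglik, digits, x$bic,
              if (is.na(x$adj_r2)) "NA" else format(round(x$adj_r2, digits))))
  if (x$degenerate) cat("  (degenerate fit)\n")
  invisible(x)
}

#' Summarise a PNP fit
#'
#' @param object a fitted [pnp()] object.
#' @param ks if `TRUE`, attach a [ks_residual_test()] of the residuals
#'   against a homogeneous Gaussian.
#' @param ... unused.
#' @return An object of class `"summary.pnp"`.
#' @export
summary.pnp <- function(object, ks = TRUE, ...) {
  out <- list(fit = object,
              n_precise = sum(object$precise),
              label = lambda_label(object$lambda),
              ks = if (ks) tryCatch(ks_residual_test(object$residuals),
                                    error = function(e) NULL))
  class(out) <- "summary.pnp"
  out
}

#' @export
print.summary.pnp <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  precise trials: %d / %d; process label: %s\n",
              x$n_precise, x$fit$n, x$label))
  if (!is.null(x$ks)) print(x$ks)
  invisible(x)
}

#' @export
coef.pnp <- function(object, ...) object$theta

#' @export
logLik.pnp <- function(object, ...) {
  structure(object$loglik, df = object$k_free, nobs = object$n,
            class = "logLik")
}

#' @export
fitted.pnp <- function(object, ...) object$fitted.values

#' @export
residuals.pnp <- function(object, ...) object$residuals

#' Predict from a fitted PNP model
#'
#' @param object a fitted [pnp()] object.
#' @param newdata optional data frame with the formula's cue variables; when
#'   omitted, the fitted values are returned.
#' @param ... unused.
#' @return Numeric vector of algorithm predictions at the fitted `theta`.
#' @export
predict.pnp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata)
  mm <- stats::model.matrix(tt, mf)
  C <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  .algo_predict(object$algorithm, C, unname(object$theta))
}

#' Simulate responses from a fitted PNP model
#'
#' Draws responses from the fitted generative process: with probability
#' `lambda` a trial's prediction is perturbed by `N(0, sigma^2)` execution
#' error, otherwise the response equals the prediction exactly.
#'
#' @param object a fitted [pnp()] object.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @param ... unused.
#' @return A data frame with `nsim` columns of simulated responses, one row
#'   per original trial.
#' @export
simulate.pnp <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
              add = TRUE)
    }
    set.seed(seed)
  }
  n <- object$n
  g <- object$fitted.values
  lam <- object$lambda
  sig <- if (object$sigma_defined) object$sigma else 0
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    b <- stats::rbinom(n, 1L, lam)
    g + ifelse(b == 1L & sig > 0, stats::rnorm(n, 0, sig), 0)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot of a PNP fit
#'
#' Left panel: responses against algorithm predictions with the identity
#' line, precise trials highlighted. Right panel: residual histogram (a
#' leptokurtic spike at zero is the signature of an Analysis-type process).
#'
#' @param x a fitted [pnp()] object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pnp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- ifelse(x$precise, "firebrick", "grey30")
  graphics::plot(x$fitted.values, x$y, col = cols,
                 xlab = "algorithm prediction", ylab = "response",
                 main = sprintf("%s (lambda = %.2f)", x$algorithm$name,
                                x$lambda), ...)
  graphics::abline(0, 1, lwd = 2)
  graphics::hist(x$residuals, breaks = "FD", main = "residuals",
                 xlab = "response - prediction")
  invisible(x)
}

#' Serialise a PNP fit to JSON
#'
#' @param fit a fitted [pnp()] object.
#' @param path optional file path; when supplied the JSON is written there.
#' @return A JSON string (class `json`), invisibly when written to a file.
#' @export
pnp_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "pnp"))
  rec <- list(theta = as.list(fit$theta),
              sigma = if (fit$sigma_defined) fit$sigma else NA,
              lambda = fit$lambda, tau = fit$tau,
              loglik = fit$loglik, n = fit$n, k_free = fit$k_free,
              bic = fit$bic, adj_r2 = fit$adj_r2,
              sigma_defined = fit$sigma_defined,
              precise_mask = fit$precise)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
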