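#' Bayesian information criterion
#'
#' `k_free * log(n) - 2 * loglik`; lower is better. For the PNP mixture the
#' free parameters are the algorithm parameters plus `sigma` and `lambda`;
#' for the homogeneous Gaussian baseline they are the algorithm parameters
#' plus `sigma`. The technical constant `tau` is fixed and never counted.
#'
#' @param loglik maximised log-likelihood.
#' @param k_free number of free parameters.
#' @param n number of trials (`n >= 1`).
#' @return The BIC value.
#' @export
bic <- function(loglik, k_free, n) {
  if (n < 1) stop("`n` must be at least 1")
  k_free * log(n) - 2 * loglik
}

#' Adjusted proportion of explained variance
#'
#' `R^2` is the squared Pearson correlation between responses and model
#' predictions, adjusted for the number of algorithm parameters:
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)`.
#'
#' @param y numeric response vector.
#' @param pred numeric prediction vector of the same length.
#' @param p number of algorithm parameters.
#' @return Adjusted R-squared (at most 1; can be negative). `NA` with a
#'   warning when the responses have zero variance.
#' @export
adjusted_r2 <- function(y, pred, p) {
  n <- length(y)
  if (length(pred) != n) stop("`y` and `pred` must have equal length")
  if (n < p + 2) stop("need at least p + 2 observations")
  if (stats::var(y) == 0) {
    warning("zero response variance: adjusted R^2 undefined")
    return(NA_real_)
  }
  r2 <- if (stats::var(pred) == 0) 0 else stats::cor(y, pred)^2
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Kolmogorov-Smirnov test of residual normality
#'
#' One-sample K-S test of the residuals against a zero-mean Gaussian with the
#' supplied scale. Under an Intuition-type process (homogeneous Gaussian
#' error) residuals should pass; the leptokurtic residuals of an
#' Analysis-type process (many exact responses plus rare large errors) are
#' rejected. The scale is plugged in rather than re-estimated under the null,
#' which makes the test anti-conservative when `sigma_hat` was estimated from
#' the same residuals.
#'
#' @param residuals numeric vector of at least 5 residuals.
#' @param sigma_hat Gaussian scale of the null; defaults to the maximum
#'   likelihood scale `sqrt(mean(residuals^2))`.
#' @return A list of class `"pnp_ks"` with elements `statistic` (D),
#'   `p.value`, `sigma`, `n` and `degenerate` (`TRUE` when the residuals have
#'   no variation, in which case the test is not computed).
#' @export
ks_residual_test <- function(residuals,
                             sigma_hat = sqrt(mean(residuals^2))) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 5L) stop("need at least 5 residuals")
  if (!all(is.finite(residuals))) stop("residuals must be finite")
  if (all(residuals == residuals[1L])) {
    out <- list(statistic = NA_real_, p.value = NA_real_,
                sigma = sigma_hat, n = length(residuals), degenerate = TRUE)
    class(out) <- "pnp_ks"
    return(out)
  }
  if (!is.finite(sigma_hat) || sigma_hat <= 0)
    stop("`sigma_hat` must be positive")
  kt <- suppressWarnings(
    stats::ks.test(residuals, "pnorm", mean = 0, sd = sigma_hat))
  out <- list(statistic = unname(kt$statistic), p.value = kt$p.value,
              sigma = sigma_hat, n = length(residuals), degenerate = FALSE)
  class(out) <- "pnp_ks"
  out
}

#' @export
print.pnp_ks <- function(x, ...) {
  if (x$degenerate) {
    cat("K-S residual test: degenerate (no residual variation)\n")
  } else {
    cat(sprintf(
      "K-S test vs N(0, %.3g^2): D = %.3f, p = %.4g (n = %d)\n",
      x$sigma, x$statistic, x$p.value, x$n))
  }
  invisible(x)
}
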