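#' Precise/not-precise mixture density
#'
#' Density of a response under the two-component PNP mixture: with
#' probability `lambda` the response is perturbed by wide Gaussian execution
#' error (sd `sigma`), otherwise it falls in the narrow "precise" band
#' (sd `tau`) around the algorithm's prediction:
#' \deqn{f(y) = \lambda N(y; g, \sigma^2) + (1-\lambda) N(y; g, \tau^2).}
#'
#' @param y numeric vector of responses.
#' @param pred numeric vector of algorithm predictions `g(x | theta)`
#'   (recycled against `y`).
#' @param lambda mixture probability of a non-precise response, in `[0, 1]`.
#' @param sigma standard deviation of the non-precise component; must be
#'   positive whenever `lambda > 0` (it may be `NA` when `lambda = 0`).
#' @param tau standard deviation of the precise component; a small technical
#'   constant, not an error estimate. Must satisfy `0 < tau < sigma`.
#' @param log if `TRUE`, return the log density (computed stably).
#' @return Numeric vector of (log) densities; strictly positive densities for
#'   finite inputs.
#' @examples
#' pnp_density(0, 0, lambda = 0.5, sigma = 1, tau = 0.001)
#' # 0.5 * dnorm(0, 0, 1) + 0.5 * dnorm(0, 0, 0.001)
#' @seealso [pnp_loglik()], [pnp()]
#' @export
pnp_density <- function(y, pred, lambda, sigma, tau, log = FALSE) {
  .check_pnp_params(lambda, sigma, tau)
  if (!all(is.finite(y)) || !all(is.finite(pred)))
    stop("`y` and `pred` must be finite")
  ll <- .pnp_ll_vec(y - pred, lambda, sigma, tau)
  if (log) ll else exp(ll)
}

.check_pnp_params <- function(lambda, sigma, tau) {
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("`lambda` must be a single value in [0, 1]")
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive value")
  if (lambda > 0) {
    if (length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
      stop("`sigma` must be a single positive value when lambda > 0")
    if (tau >= sigma)
      stop("`tau` must be smaller than `sigma`")
  }
  invisible(TRUE)
}

# stable per-trial log density of residuals under the mixture
.pnp_ll_vec <- function(e, lambda, sigma, tau) {
  if (lambda >= 1) return(stats::dnorm(e, 0, sigma, log = TRUE))
  if (lambda <= 0) return(stats::dnorm(e, 0, tau, log = TRUE))
  la <- log(lambda) + stats::dnorm(e, 0, sigma, log = TRUE)
  lb <- log1p(-lambda) + stats::dnorm(e, 0, tau, log = TRUE)
  m <- pmax(la, lb)
  m + log(exp(la - m) + exp(lb - m))
}

#' Joint log-likelihood under the PNP mixture
#'
#' Sums the log mixture density over independent trials. This is the
#' objective maximised by [pnp()].
#'
#' @inheritParams pnp_density
#' @return A single number: `sum(log f(y_i))`.
#' @examples
#' y <- c(1, 1); p <- c(1, 1)
#' pnp_loglik(y, p, lambda = 1, sigma = 2, tau = 1e-3) ==
#'   sum(dnorm(y, p, 2, log = TRUE))
#' @export
pnp_loglik <- function(y, pred, lambda, sigma, tau) {
  sum(pnp_density(y, pred, lambda, sigma, tau, log = TRUE))
}
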