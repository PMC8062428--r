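#' Reference cognitive algorithms
#'
#' Constructs a reference algorithm `g(x | theta)`: the candidate cognitive
#' computation that maps a vector of numeric cues to a judgment. The
#' precise/not-precise mixture (see [pnp()]) is always fitted *relative to*
#' such an algorithm; a "precise" response is one that equals the algorithm's
#' output exactly.
#'
#' Available algorithms:
#' \describe{
#'   \item{`linear_additive`}{`alpha + beta_1 x_1 + ... + beta_k x_k`, the
#'     default additive cue-integration rule. Any number of cues.}
#'   \item{`area_scaled`}{`alpha + beta * x`, a linearly scaled single cue
#'     (e.g. the true area of a stimulus), capturing both biased and
#'     unbiased (`alpha = 0`, `beta = 1`) estimates.}
#'   \item{`product`}{`alpha + beta * (x_1 * x_2)`, the linearly adjusted
#'     product of two cues (e.g. multiplicand 1 and multiplicand 2).}
#'   \item{`dividend_m1`}{`alpha + beta * (x_1 / x_2)`, for inferring the
#'     first multiplicand from cues (product, M2).}
#'   \item{`dividend_m2`}{`alpha + beta * (x_1 / x_2)`, for inferring the
#'     second multiplicand from cues (product, M1).}
#'   \item{`expected_value`}{`alpha + beta * (probability * reward)`, the
#'     linearly adjusted expected value of a gamble with cues
#'     (probability, reward).}
#'   \item{`nonadditive_exp`}{the fixed nonadditive criterion function
#'     `509.05 + 0.54 * exp((4 x_1 + 3 x_2 + 2 x_3 + 1 x_4) / 18)` over four
#'     cues. It has no free parameters.}
#'   \item{`exemplar`}{a similarity-weighted average of stored exemplar
#'     criteria (a generalized context model for a continuous criterion),
#'     with sensitivity `delta` and attention weights `omega_1..omega_k`
#'     constrained to the unit simplex. Requires `exemplars` and
#'     `criteria`.}
#' }
#'
#' @param name algorithm name (see Details).
#' @param ncue number of cue columns, for `linear_additive` when it cannot be
#'   inferred from data. Other algorithms have a fixed cue count.
#' @param exemplars numeric matrix of stored exemplar cue vectors (one row per
#'   exemplar); `exemplar` only.
#' @param criteria numeric vector of criterion values `c_j`, one per exemplar
#'   row; `exemplar` only.
#' @return An object of class `"pnp_algorithm"` with fields `name`, `npar`
#'   (number of parameters in `theta`), `nfree` (parameters counted as free
#'   when penalising fit; equals `npar` except for the exemplar model, whose
#'   attention weights lose one degree of freedom to the simplex constraint),
#'   `param_names`, `linear` (linear in `theta`, enabling exact solves) and
#'   `min_subset` (minimal number of trials for an exact solve).
#' @examples
#' a <- pnp_algorithm("linear_additive", ncue = 4)
#' predict(a, matrix(0, 1, 4), theta = c(50, 4, 3, 2, 1))  # 50
#'
#' ev <- pnp_algorithm("expected_value")
#' predict(ev, cbind(0.5, 100), theta = c(0, 1.61))        # 80.5
#' @seealso [pnp()], [exact_solve()]
#' @export
pnp_algorithm <- function(name = c("linear_additive", "area_scaled", "product",
                                   "dividend_m1", "dividend_m2",
                                   "expected_value", "nonadditive_exp",
                                   "exemplar"),
                          ncue = NULL, exemplars = NULL, criteria = NULL) {
  name <- match.arg(name)
  algo <- switch(name,
    linear_additive = list(
      name = name, ncue = if (is.null(ncue)) NA_integer_ else as.integer(ncue),
      linear = TRUE,
      features = function(C) cbind(1, C)),
    area_scaled = list(
      name = name, ncue = 1L, linear = TRUE,
      features = function(C) cbind(1, C[, 1L])),
    product = ,
    expected_value = list(
      name = name, ncue = 2L, linear = TRUE,
      features = function(C) cbind(1, C[, 1L] * C[, 2L])),
    dividend_m1 = ,
    dividend_m2 = list(
      name = name, ncue = 2L, linear = TRUE,
      features = function(C) {
        bad <- which(abs(C[, 2L]) < 1e-12)
        if (length(bad))
          stop("zero divisor in trial(s): ", paste(bad, collapse = ", "),
               call. = FALSE)
        cbind(1, C[, 1L] / C[, 2L])
      }),
    nonadditive_exp = list(
      name = name, ncue = 4L, linear = FALSE, fixed = TRUE,
      predict_fn = function(C, theta)
        509.05 + 0.54 * exp((4 * C[, 1L] + 3 * C[, 2L] +
                             2 * C[, 3L] + 1 * C[, 4L]) / 18)),
    exemplar = {
      if (is.null(exemplars) || is.null(criteria))
        stop("the exemplar algorithm requires `exemplars` and `criteria`")
      exemplars <- as.matrix(exemplars)
      storage.mode(exemplars) <- "double"
      criteria <- as.numeric(criteria)
      if (nrow(exemplars) < 1L)
        stop("at least one exemplar is required")
      if (nrow(exemplars) != length(criteria))
        stop("`criteria` must have one value per exemplar row")
      if (!all(is.finite(exemplars)) || !all(is.finite(criteria)))
        stop("exemplars and criteria must be finite")
      list(name = name, ncue = ncol(exemplars), linear = FALSE,
           exemplars = exemplars, criteria = criteria)
    })
  algo$fixed <- isTRUE(algo$fixed)
  algo <- .algo_finalize(algo)
  class(algo) <- "pnp_algorithm"
  algo
}

# fill in parameter metadata once the cue count is known
.algo_finalize <- function(algo) {
  k <- algo$ncue
  if (algo$name == "linear_additive" && !is.na(k)) {
    algo$param_names <- c("alpha", paste0("beta_", seq_len(k)))
  } else if (algo$name %in% c("area_scaled", "product", "dividend_m1",
                              "dividend_m2", "expected_value")) {
    algo$param_names <- c("alpha", "beta")
  } else if (algo$name == "nonadditive_exp") {
    algo$param_names <- character(0)
  } else if (algo$name == "exemplar") {
    algo$param_names <- c("delta", paste0("omega_", seq_len(k)))
  }
  algo$npar <- length(algo$param_names)
  algo$nfree <- if (algo$name == "exemplar") algo$npar - 1L else algo$npar
  algo$min_subset <- if (isTRUE(algo$linear)) algo$npar else NA_integer_
  algo
}

# accept a name or a pnp_algorithm and bind it to a concrete cue matrix
.resolve_algorithm <- function(algorithm, C) {
  if (is.character(algorithm))
    algorithm <- pnp_algorithm(algorithm,
                               ncue = if (algorithm == "linear_additive")
                                 ncol(C) else NULL)
  if (!inherits(algorithm, "pnp_algorithm"))
    stop("`algorithm` must be an algorithm name or a 'pnp_algorithm' object")
  if (is.na(algorithm$ncue)) {
    algorithm$ncue <- ncol(C)
    algorithm <- .algo_finalize(algorithm)
    class(algorithm) <- "pnp_algorithm"
  }
  if (ncol(C) != algorithm$ncue)
    stop(sprintf("algorithm '%s' expects %d cue column(s), got %d",
                 algorithm$name, algorithm$ncue, ncol(C)))
  algorithm
}

#' Predict from a reference algorithm
#'
#' Evaluates `g(x | theta)` for each row of a cue matrix.
#'
#' @param object a [pnp_algorithm()] object.
#' @param cues numeric matrix (or data frame) of cue values, one trial per row.
#' @param theta numeric parameter vector (empty for `nonadditive_exp`). For
#'   the exemplar algorithm, `theta = c(delta, omega_1, ..., omega_k)`.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.pnp_algorithm <- function(object, cues, theta = numeric(0), ...) {
  C <- as.matrix(cues)
  storage.mode(C) <- "double"
  object <- .resolve_algorithm(object, C)
  theta <- as.numeric(theta)
  if (length(theta) != object$npar)
    stop(sprintf("algorithm '%s' expects %d parameter(s), got %d",
                 object$name, object$npar, length(theta)))
  if (object$npar > 0 && !all(is.finite(theta)))
    stop("`theta` must be finite")
  .algo_predict(object, C, theta)
}

.algo_predict <- function(algo, C, theta) {
  if (isTRUE(algo$linear))
    return(drop(algo$features(C) %*% theta))
  if (isTRUE(algo$fixed))
    return(algo$predict_fn(C, theta))
  # exemplar
  .exemplar_predict(C, algo$exemplars, algo$criteria,
                    delta = theta[1L], omega = theta[-1L])
}

# similarity-weighted average of exemplar criteria; city-block similarity
# exp(-delta * sum_i omega_i |x_i - x*_ji|). Probes whose similarities all
# underflow to zero fall back to the unweighted mean (flagged via attribute).
.exemplar_predict <- function(C, E, crit, delta, omega) {
  if (delta < 0 || any(omega < 0))
    stop("exemplar sensitivity and weights must be nonnegative")
  n <- nrow(C); J <- nrow(E)
  S <- matrix(0, n, J)
  for (j in seq_len(J)) {
    d <- abs(C - matrix(E[j, ], n, ncol(C), byrow = TRUE)) %*% omega
    S[, j] <- exp(-delta * d)
  }
  tot <- rowSums(S)
  out <- numeric(n)
  ok <- tot > 0
  if (any(ok)) out[ok] <- (S[ok, , drop = FALSE] %*% crit) / tot[ok]
  if (any(!ok)) {
    out[!ok] <- mean(crit)
    attr(out, "underflow") <- which(!ok)
  }
  out
}

#' Exactly solve a linear algorithm on a minimal trial subset
#'
#' For algorithms that are linear in `theta`, finds the parameter vector that
#' reproduces the responses of a minimal subset of trials exactly (the
#' building block of the exact-fit search used by [pnp()]).
#'
#' @param algorithm a [pnp_algorithm()] object or name; must be linear in
#'   `theta`.
#' @param cues numeric cue matrix with exactly `min_subset` rows.
#' @param y numeric response vector of the same length.
#' @return The solving parameter vector, or `NULL` when the subset's design
#'   matrix is singular (e.g. duplicated trials).
#' @examples
#' exact_solve("expected_value", cbind(c(.5, .2), c(100, 50)), c(50, 10))
#' @export
exact_solve <- function(algorithm, cues, y) {
  C <- as.matrix(cues)
  storage.mode(C) <- "double"
  algo <- .resolve_algorithm(algorithm, C)
  if (!isTRUE(algo$linear))
    stop(sprintf("algorithm '%s' has no exact solve", algo$name))
  y <- as.numeric(y)
  if (nrow(C) != algo$min_subset || length(y) != algo$min_subset)
    stop(sprintf("exact solve needs exactly %d trial(s)", algo$min_subset))
  F <- algo$features(C)
  th <- tryCatch(solve(F, y), error = function(e) NULL)
  if (!is.null(th) && !all(is.finite(th))) th <- NULL
  if (!is.null(th)) names(th) <- algo$param_names
  th
}

#' @export
print.pnp_algorithm <- function(x, ...) {
  cat(sprintf("Reference algorithm '%s'\n", x$name))
  cat(sprintf("  cues: %s, parameters: %s\n",
              ifelse(is.na(x$ncue), "any", x$ncue),
              if (x$npar == 0) "none (fixed)"
              else paste(x$param_names, collapse = ", ")))
  if (x$name == "exemplar")
    cat(sprintf("  exemplar store: %d exemplars\n", nrow(x$exemplars)))
  invisible(x)
}

#' Names of the available reference algorithms
#' @return Character vector of algorithm names accepted by [pnp_algorithm()].
#' @export
list_algorithms <- function() {
  c("linear_additive", "area_scaled", "product", "dividend_m1",
    "dividend_m2", "expected_value", "nonadditive_exp", "exemplar")
}
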