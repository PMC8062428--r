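#' Test-retest reliability of repeated judgments
#'
#' Pearson correlation between the first and second presentation of each
#' item: the classical estimate of the proportion of systematic ("true")
#' variance in the responses, used as the denominator of the saturation
#' index.
#'
#' @param data data frame of one participant's trials.
#' @param response,item,repetition column names.
#' @return The reliability coefficient `rho` in `[-1, 1]`.
#' @seealso [saturation_index()]
#' @export
estimate_reliability <- function(data, response = "response",
                                 item = "item_id",
                                 repetition = "repetition") {
  for (col in c(response, item, repetition))
    if (!col %in% names(data)) stop(sprintf("missing column '%s'", col))
  reps <- sort(unique(data[[repetition]]))
  counts <- table(data[[item]])
  bad <- names(counts)[counts != 2L]
  if (length(reps) != 2L || length(bad))
    stop("every item needs exactly 2 repetitions; offending item(s): ",
         if (length(bad)) paste(bad, collapse = ", ")
         else "(repetition index not binary)")
  d1 <- data[data[[repetition]] == reps[1L], ]
  d2 <- data[data[[repetition]] == reps[2L], ]
  d1 <- d1[order(d1[[item]]), ]
  d2 <- d2[order(d2[[item]]), ]
  if (!identical(d1[[item]], d2[[item]]))
    stop("items do not pair across the two repetitions")
  stats::cor(d1[[response]], d2[[response]])
}

#' Saturation index
#'
#' `SI = R^2 / rho`: the share of the systematic (test-retest reliable)
#' variance that a model explains. `SI` near 1 means the model saturates the
#' data — it accounts for essentially all the true variance — while a low
#' `SI` signals residual systematicity the model fails to capture, even when
#' raw `R^2` looks acceptable.
#'
#' @param r2 model R-squared (proportion of total variance explained).
#' @param rho reliability coefficient (proportion of true variance), `> 0`.
#' @return `r2 / rho`. Values above 1 (a finite-sample artifact) are
#'   returned with a warning; `rho <= 0` gives `NA` with a warning.
#' @examples
#' saturation_index(0.50, 0.90)  # 0.56: the model misses true variance
#' saturation_index(0.90, 0.90)  # 1: the model saturates the data
#' @export
saturation_index <- function(r2, rho) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1)
    stop("`r2` must be in [0, 1]")
  if (!is.finite(rho) || rho <= 0) {
    warning("non-positive reliability: saturation index undefined")
    return(NA_real_)
  }
  si <- r2 / rho
  if (si > 1)
    warning("saturation index above 1 (sampling artifact)")
  si
}

#' Label the process type from the error probability
#'
#' Maps fitted `lambda` values to the process labels suggested by their
#' empirical bimodal distribution: `"analysis"` for `lambda < 0.1` (mostly
#' exact executions with rare errors), `"intuition"` for `lambda > 0.8`
#' (ubiquitous Gaussian error), `"mixed"` otherwise.
#'
#' @param lambda numeric vector of mixture probabilities in `[0, 1]`.
#' @return Character vector of labels.
#' @export
lambda_label <- function(lambda) {
  ifelse(lambda < 0.1, "analysis",
         ifelse(lambda > 0.8, "intuition", "mixed"))
}

#' Classify a participant's judgment strategy
#'
#' Fits the precise/not-precise mixture once per candidate reference
#' algorithm and selects the algorithm with the lowest BIC (ties go to the
#' candidate with fewer free parameters, then to the linear-additive rule,
#' then to candidate order). The winning fit is labelled by its error
#' probability ([lambda_label()]), and — when the data contain two
#' repetitions per item — the saturation index of the winning algorithm is
#' attached, together with a residual-normality test.
#'
#' @param formula model formula `response ~ cues...` shared by all
#'   candidates.
#' @param data one participant's trials.
#' @param algorithms candidate algorithms: a character vector of names
#'   and/or a (optionally named) list of [pnp_algorithm()] objects.
#' @param tau fixed precise-component sd (default: the
#'   `sd(response) * 1e-3` convention).
#' @param control a [pnp_control()] list.
#' @return An object of class `"pnp_select"`: list with `best` (winning
#'   algorithm name), `fit` (its [pnp()] fit), `fits` (all successful fits),
#'   `table` (per-candidate BIC summary), `label`, `rho`, `si`, `ks_p` and
#'   `errors` (messages of failed candidate fits; if every candidate fails
#'   the object records the failure instead of a classification).
#' @examples
#' d <- simulate_participant("product", c(0, 1), lambda = 0.05, sigma = 8,
#'                           n = 32, cue_min = c(.1, 10), cue_max = c(.8, 80),
#'                           seed = 2)
#' sel <- select_model(response ~ cue_1 + cue_2, d,
#'                     algorithms = c("product", "linear_additive"))
#' sel$best; sel$label
#' @export
select_model <- function(formula, data,
                         algorithms = c("product", "linear_additive"),
                         tau = NULL, control = pnp_control()) {
  if (length(algorithms) < 2L) stop("need at least 2 candidate algorithms")
  if (!is.list(algorithms)) algorithms <- as.list(algorithms)
  nm <- names(algorithms)
  if (is.null(nm)) nm <- rep("", length(algorithms))
  for (i in seq_along(algorithms)) if (nm[i] == "")
    nm[i] <- if (is.character(algorithms[[i]])) algorithms[[i]]
             else algorithms[[i]]$name
  names(algorithms) <- make.unique(nm)

  fits <- list()
  errors <- character(0)
  for (i in seq_along(algorithms)) {
    f <- tryCatch(pnp(formula, data, algorithm = algorithms[[i]], tau = tau,
                      control = control),
                  error = function(e) conditionMessage(e))
    if (inherits(f, "pnp")) fits[[names(algorithms)[i]]] <- f
    else errors[names(algorithms)[i]] <- f
  }
  if (!length(fits)) {
    out <- list(best = NA_character_, fit = NULL, fits = list(),
                table = NULL, label = NA_character_, rho = NA_real_,
                si = NA_real_, ks_p = NA_real_, errors = errors)
    class(out) <- "pnp_select"
    return(out)
  }
  tab <- data.frame(
    algorithm = names(fits),
    k_free = vapply(fits, `[[`, numeric(1), "k_free"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    lambda = vapply(fits, `[[`, numeric(1), "lambda"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    row.names = NULL)
  # lowest BIC; deterministic tie-break: fewer parameters, then the additive
  # rule, then candidate order
  additive_rank <- ifelse(tab$algorithm == "linear_additive", 0L, 1L)
  o <- order(round(tab$bic, 8), tab$k_free, additive_rank,
             seq_len(nrow(tab)))
  best_name <- tab$algorithm[o[1L]]
  best <- fits[[best_name]]

  rho <- tryCatch(estimate_reliability(data), error = function(e) NA_real_)
  si <- if (!is.na(rho) && rho > 0 && !is.na(best$adj_r2)) {
    r2 <- if (stats::var(best$fitted.values) > 0)
      stats::cor(best$y, best$fitted.values)^2 else 0
    suppressWarnings(saturation_index(min(r2, 1), rho))
  } else NA_real_
  ks <- tryCatch(ks_residual_test(best$residuals), error = function(e) NULL)
  out <- list(best = best_name, fit = best, fits = fits, table = tab,
              label = lambda_label(best$lambda), rho = rho, si = si,
              ks_p = if (!is.null(ks) && !ks$degenerate) ks$p.value
                     else NA_real_,
              errors = errors)
  class(out) <- "pnp_select"
  out
}

#' @export
print.pnp_select <- function(x, digits = 3, ...) {
  if (is.na(x$best)) {
    cat("Strategy classification failed for all candidates:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[nm]))
    return(invisible(x))
  }
  cat("Strategy classification (lowest BIC wins)\n")
  tab <- x$table
  tab[c("loglik", "bic", "lambda", "adj_r2")] <-
    round(tab[c("loglik", "bic", "lambda", "adj_r2")], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Best: %s; process label: %s (lambda = %s)\n", x$best,
              x$label, format(round(x$fit$lambda, digits))))
  if (!is.na(x$si))
    cat(sprintf("Reliability rho = %.3f; saturation index = %.3f\n",
                x$rho, x$si))
  if (!is.na(x$ks_p))
    cat(sprintf("K-S residual-normality p = %.4g\n", x$ks_p))
  invisible(x)
}

#' Summarise a cohort of classified participants
#'
#' Aggregates per-participant strategy classifications into
#' condition-level summaries: best-algorithm counts, process-label counts,
#' and medians of `lambda`, `sigma`, adjusted `R^2` and the saturation
#' index. The `sigma` median is computed only over fits in which errors
#' actually occurred (participants with zero error variance are excluded).
#' A second table gives median algorithm parameters per condition and
#' best-fitting algorithm.
#'
#' @param classifications a list of [select_model()] results (or a single
#'   one).
#' @param condition optional character vector, one condition label per
#'   classification; defaults to a single condition.
#' @return A list of class `"pnp_cohort"` with data frames `summary` (one
#'   row per condition) and `parameters` (one row per condition and
#'   best-fitting algorithm, with median `theta` components).
#' @export
cohort_summary <- function(classifications, condition = NULL) {
  if (inherits(classifications, "pnp_select"))
    classifications <- list(classifications)
  ok <- vapply(classifications, function(x) !is.na(x$best), logical(1))
  if (!any(ok)) stop("no successful classifications to summarise")
  cls <- classifications[ok]
  condition <- if (is.null(condition)) rep("all", length(classifications))
               else rep_len(as.character(condition), length(classifications))
  condition <- condition[ok]

  rows <- data.frame(
    condition = condition,
    algorithm = vapply(cls, `[[`, character(1), "best"),
    lambda = vapply(cls, function(x) x$fit$lambda, numeric(1)),
    sigma = vapply(cls, function(x)
      if (x$fit$sigma_defined) x$fit$sigma else NA_real_, numeric(1)),
    adj_r2 = vapply(cls, function(x) x$fit$adj_r2, numeric(1)),
    si = vapply(cls, `[[`, numeric(1), "si"),
    label = vapply(cls, `[[`, character(1), "label"))

  med <- function(v) if (any(!is.na(v))) stats::median(v, na.rm = TRUE)
                     else NA_real_
  summ <- do.call(rbind, lapply(split(rows, rows$condition), function(d) {
    counts <- table(d$algorithm)
    data.frame(condition = d$condition[1L], n = nrow(d),
               median_lambda = med(d$lambda), median_sigma = med(d$sigma),
               median_adj_r2 = med(d$adj_r2), median_si = med(d$si),
               n_analysis = sum(d$label == "analysis"),
               n_mixed = sum(d$label == "mixed"),
               n_intuition = sum(d$label == "intuition"),
               best_counts = paste(sprintf("%s=%d", names(counts), counts),
                                   collapse = "; "))
  }))
  rownames(summ) <- NULL

  par_rows <- unlist(recursive = FALSE, lapply(
    split(seq_along(cls), condition), function(ix) {
    lapply(split(ix, vapply(cls[ix], `[[`, character(1), "best")),
           function(jx) {
      TH <- do.call(rbind, lapply(cls[jx], function(x) x$fit$theta))
      d <- data.frame(condition = condition[jx[1L]],
                      algorithm = cls[[jx[1L]]]$best, n = length(jx))
      if (!is.null(TH) && ncol(TH))
        d <- cbind(d, as.data.frame(t(apply(TH, 2L, stats::median))))
      d
    })
  }))
  # algorithms differ in their parameter sets; fill absent columns with NA
  all_cols <- unique(unlist(lapply(par_rows, names)))
  pars <- do.call(rbind, lapply(par_rows, function(d) {
    for (col in setdiff(all_cols, names(d))) d[[col]] <- NA
    d[all_cols]
  }))
  rownames(pars) <- NULL

  out <- list(summary = summ, parameters = pars, participants = rows)
  class(out) <- "pnp_cohort"
  out
}

#' @export
print.pnp_cohort <- function(x, digits = 3, ...) {
  cat("Cohort summary (medians per condition)\n")
  s <- x$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- round(s[num], digits)
  print(s, row.names = FALSE)
  invisible(x)
}
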