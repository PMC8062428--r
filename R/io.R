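#' Read a judgment dataset from delimited text
#'
#' Reads long-format judgment data with a header row and columns
#' `participant_id`, `item_id`, `repetition`, one or more cue columns
#' (`cue_1`, `cue_2`, ... by default) and `response`; an optional
#' `condition` column is kept. Comma and tab delimiters are auto-detected.
#' Validation errors (missing columns, non-numeric cells, duplicated
#' participant/item/repetition keys) report the offending file line numbers.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` auto-detects `","` versus `"\t"`.
#' @param cues cue column names; default all columns matching `^cue_`.
#' @return A validated data frame with attribute `"cues"` naming the cue
#'   columns.
#' @seealso [write_judgment_data()], [make_fixture()]
#' @export
read_judgment_data <- function(path, sep = NULL, cues = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (!length(first)) stop("empty file (no header row)")
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(cues)) cues <- grep("^cue_", names(raw), value = TRUE)
  required <- c("participant_id", "item_id", "repetition", "response")
  missing_cols <- setdiff(c(required, cues), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!length(cues)) stop("no cue column(s) found (expected cue_1, ...)")

  out <- raw
  for (col in c("repetition", cues, "response")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value(s) in column '%s' at line(s): %s",
                   col, paste(bad + 1L, collapse = ", ")))
    out[[col]] <- v
  }
  key <- paste(out$participant_id, out$item_id, out$repetition, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicated (participant, item, repetition) key(s) at line(s): ",
         paste(dup + 1L, collapse = ", "))
  attr(out, "cues") <- cues
  out
}

#' Write a judgment dataset to delimited text
#'
#' Numeric columns are serialised at full double precision (17 significant
#' digits), so a write/read round trip is value-exact.
#'
#' @param data data frame as produced by [simulate_participant()] or
#'   [read_judgment_data()].
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_judgment_data <- function(data, path, sep = ",") {
  out <- data
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Built-in synthetic fixture scenarios
#'
#' Reproducible synthetic datasets mirroring the package's worked examples
#' and simulation designs:
#' \describe{
#'   \item{`id24_like`}{32 lotteries (probability and reward cues). 25
#'     responses equal the expected value exactly; 7 seeded trials are
#'     perturbed by `N(0, 92.6^2)`. An Analysis-type participant: fitting
#'     the `expected_value` algorithm with `tau = 1e-3` recovers
#'     `alpha = 0`, `beta = 1` and `lambda = 7/32 = .219`.}
#'   \item{`id84_like`}{the same 32 lotteries; every response is a damped
#'     expected value (`beta = 0.75`) plus moderate Gaussian noise, so no
#'     response matches any line exactly — an Intuition-type participant
#'     (`lambda = 1`).}
#'   \item{`recovery_cell`}{one simulated participant of the recovery
#'     design: 50 trials of the linear-additive rule with
#'     `theta = (50, 4, 3, 2, 1)`, cues uniform on `[0, 10]`, error sd 10
#'     and error probability `lambda`.}
#'   \item{`bimodal_cohort`}{30 recovery-style participants: 15 with
#'     `lambda = 0.05` (Analysis-type) and 15 with `lambda = 1`
#'     (Intuition-type), with a `condition` column.}
#' }
#'
#' @param kind scenario name.
#' @param seed integer seed.
#' @param lambda error probability for `recovery_cell`.
#' @param path optional file path; when given, the fixture is written with
#'   [write_judgment_data()].
#' @return The fixture data frame (invisibly when written to a file), with
#'   attribute `"params"` documenting the generating parameters.
#' @export
make_fixture <- function(kind = c("id24_like", "id84_like", "recovery_cell",
                                  "bimodal_cohort"),
                         seed = 1L, lambda = 0.5, path = NULL) {
  kind <- match.arg(kind)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)
  out <- switch(kind,
    id24_like = ,
    id84_like = {
      grid <- expand.grid(probability = seq(0.1, 0.8, by = 0.1),
                          reward = seq(10, 80, by = 10))
      pick <- sort(sample.int(nrow(grid), 32L))
      C <- grid[pick, ]
      ev <- C$probability * C$reward
      if (kind == "id24_like") {
        noisy <- sort(sample.int(32L, 7L))
        response <- ev
        response[noisy] <- ev[noisy] + stats::rnorm(7L, 0, 92.6)
        params <- list(theta = c(alpha = 0, beta = 1), lambda = 7 / 32,
                       sigma = 92.6, noisy = noisy, tau = 1e-3)
        precise <- !(seq_len(32L) %in% noisy)
      } else {
        response <- 0.75 * ev + stats::rnorm(32L, 0, 10)
        params <- list(theta = c(alpha = 0, beta = 0.75), lambda = 1,
                       sigma = 10, tau = 1e-3)
        precise <- rep(FALSE, 32L)
      }
      d <- data.frame(participant_id = if (kind == "id24_like") 24L else 84L,
                      item_id = seq_len(32L), repetition = 1L,
                      cue_1 = C$probability, cue_2 = C$reward,
                      response = response)
      attr(d, "precise") <- precise
      attr(d, "params") <- c(params, list(algorithm = "expected_value"))
      d
    },
    recovery_cell = simulate_participant(
      "linear_additive", c(50, 4, 3, 2, 1), lambda = lambda, sigma = 10,
      n = 50, cue_min = 0, cue_max = 10, seed = seed),
    bimodal_cohort = {
      parts <- lapply(seq_len(30L), function(p) {
        lam <- if (p <= 15L) 0.05 else 1
        d <- simulate_participant("linear_additive", c(50, 4, 3, 2, 1),
                                  lambda = lam, sigma = 10, n = 50,
                                  participant = p,
                                  seed = participant_seed(seed, p))
        d$condition <- if (p <= 15L) "analysis" else "intuition"
        d
      })
      d <- do.call(rbind, parts)
      attr(d, "params") <- list(theta = c(50, 4, 3, 2, 1),
                                lambda = c(analysis = 0.05, intuition = 1),
                                sigma = 10)
      d
    })
  if (!is.null(path)) {
    write_judgment_data(out, path)
    return(invisible(out))
  }
  out
}
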