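test_that("test-retest reliability matches classical test theory", {
  base <- simulate_participant("linear_additive", c(50, 4, 3, 2, 1), 1, 10,
                               n = 25, repetition = 1, seed = 71)
  # identical repetitions: rho = 1
  d2 <- base
  d2$repetition <- 2
  expect_equal(estimate_reliability(rbind(base, d2)), 1)
  # mirrored around the mean: rho = -1
  d3 <- base
  d3$repetition <- 2
  d3$response <- -(base$response - mean(base$response)) + mean(base$response)
  expect_equal(estimate_reliability(rbind(base, d3)), -1)
  # true scores plus independent noise: rho ~ true-variance share
  set.seed(72)
  m <- 4000
  true_scores <- rnorm(m, 100, 10)          # var 100
  noise_sd <- 5                             # var 25 -> rho = 100 / 125 = .8
  dd <- data.frame(
    participant_id = 1, item_id = rep(seq_len(m), 2),
    repetition = rep(1:2, each = m), cue_1 = 0,
    response = rep(true_scores, 2) + rnorm(2 * m, 0, noise_sd))
  expect_equal(estimate_reliability(dd), 100 / 125, tolerance = 0.03)
})

test_that("reliability demands exactly two repetitions per item", {
  d <- simulate_participant("linear_additive", c(1, 2), 1, 5, n = 6,
                            seed = 73)
  expect_error(estimate_reliability(d), "exactly 2 repetitions")
  d2 <- rbind(d, transform(d, repetition = 2))
  expect_error(estimate_reliability(d2[-1, ]), "offending item.*1")
})

test_that("saturation index is the reliable-variance share explained", {
  expect_equal(round(saturation_index(0.50, 0.90), 2), 0.56)
  expect_identical(saturation_index(0.90, 0.90), 1)
  expect_identical(saturation_index(0, 0.9), 0)
  expect_warning(out <- saturation_index(0.9, -0.1), "undefined")
  expect_true(is.na(out))
  expect_warning(saturation_index(0.99, 0.9), "above 1")
})

test_that("lambda labels follow the bimodal cutpoints exactly", {
  expect_identical(lambda_label(c(0, 0.0999, 0.1, 0.5, 0.8, 0.8001, 1)),
                   c("analysis", "analysis", "mixed", "mixed", "mixed",
                     "intuition", "intuition"))
})

test_that("model selection recovers the generating strategy", {
  # precise multiplicative integration -> product algorithm, analysis label
  d_mult <- simulate_participant("product", c(0, 1), lambda = 0.06,
                                 sigma = 8, n = 32, cue_min = c(0.1, 10),
                                 cue_max = c(0.8, 80), seed = 74)
  s1 <- select_model(response ~ cue_1 + cue_2, d_mult,
                     algorithms = c("product", "linear_additive"))
  expect_identical(s1$best, "product")
  expect_identical(s1$label, "analysis")
  expect_lt(s1$ks_p, 0.001)

  # noisy additive integration -> additive algorithm, intuition label
  d_add <- simulate_participant("linear_additive", c(5, 2, 3), lambda = 1,
                                sigma = 6, n = 40, cue_min = c(0.1, 10),
                                cue_max = c(0.8, 80), seed = 75)
  s2 <- select_model(response ~ cue_1 + cue_2, d_add,
                     algorithms = c("product", "linear_additive"))
  expect_identical(s2$best, "linear_additive")
  expect_identical(s2$label, "intuition")
  expect_output(print(s2), "lowest BIC")
})

test_that("selection separates the additive and product strategies reliably", {
  hits <- 0L
  for (seed in 1:10) {
    gen <- if (seed %% 2 == 0) "product" else "linear_additive"
    d <- simulate_participant(gen,
                              if (gen == "product") c(0, 1) else c(5, 2, 3),
                              lambda = if (gen == "product") 0.05 else 1,
                              sigma = if (gen == "product") 8 else 6,
                              n = 32, cue_min = c(0.1, 10),
                              cue_max = c(0.8, 80), seed = 760 + seed)
    s <- select_model(response ~ cue_1 + cue_2, d,
                      algorithms = c("product", "linear_additive"))
    hits <- hits + (s$best == gen)
  }
  expect_gte(hits, 10L * 0.95)
})

test_that("BIC ties break deterministically on duplicated candidates", {
  d <- simulate_participant("product", c(0, 1), 0.1, 8, n = 24,
                            cue_min = c(0.1, 10), cue_max = c(0.8, 80),
                            seed = 77)
  s <- select_model(response ~ cue_1 + cue_2, d,
                    algorithms = list(a = "product", b = "product"))
  expect_identical(s$best, "a")
  s2 <- select_model(response ~ cue_1 + cue_2, d,
                     algorithms = list(a = "product", b = "product"))
  expect_identical(s2$best, "a")
})

test_that("selection attaches the saturation index when items repeat", {
  th <- c(50, 4, 3, 2, 1)
  r1 <- simulate_participant("linear_additive", th, 0, 10, n = 25,
                             repetition = 1, seed = 78)
  r2 <- r1
  r2$repetition <- 2
  d <- rbind(r1, r2)   # noise-free, repeated: the model saturates the data
  s <- select_model(response ~ cue_1 + cue_2 + cue_3 + cue_4, d,
                    algorithms = c("linear_additive", "nonadditive_exp"))
  expect_equal(s$rho, 1)
  expect_equal(s$si, 1, tolerance = 1e-9)
})

test_that("cohort summaries apply the error-occurrence rule for sigma", {
  one <- mock_selection(lambda = 0.3, sigma = 12)
  cs1 <- cohort_summary(list(one))
  expect_identical(cs1$summary$median_lambda, 0.3)
  expect_identical(cs1$summary$median_sigma, 12)

  trio <- list(
    mock_selection(lambda = 0, sigma = NA, sigma_defined = FALSE),
    mock_selection(lambda = 0.5, sigma = 6),
    mock_selection(lambda = 1, sigma = 10))
  cs3 <- cohort_summary(trio)
  # sigma median over the two fits in which errors actually occurred
  expect_identical(cs3$summary$median_sigma, 8)
  expect_identical(cs3$summary$n_analysis, 1L)
  expect_identical(cs3$summary$n_intuition, 1L)
})

test_that("a bimodal cohort round-trips through classification", {
  coh <- make_fixture("bimodal_cohort", seed = 79)
  sels <- lapply(split(coh, coh$participant_id), function(d)
    select_model(response ~ cue_1 + cue_2 + cue_3 + cue_4, d,
                 algorithms = c("linear_additive", "nonadditive_exp")))
  cond <- vapply(split(coh, coh$participant_id),
                 function(d) d$condition[1], character(1))
  cs <- cohort_summary(sels, condition = cond)
  lam <- cs$participants$lambda
  # mass below .1 and above .8, nothing substantial in between
  expect_gte(sum(lam < 0.1), 13)
  expect_gte(sum(lam > 0.8), 13)
  s <- cs$summary[cs$summary$condition == "analysis", ]
  expect_lt(s$median_lambda, 0.1)
  s2 <- cs$summary[cs$summary$condition == "intuition", ]
  expect_gt(s2$median_lambda, 0.8)
  # the generating additive rule wins for nearly everyone
  best <- cs$participants$algorithm
  expect_gte(mean(best == "linear_additive"), 0.9)
})
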