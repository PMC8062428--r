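test_that("an Analysis-type worked example recovers lambda as a trial share", {
  d <- make_fixture("id24_like", seed = 3)
  f <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-3)
  # 25 of 32 responses are exact expected values; 7 carry large errors
  expect_equal(f$lambda, 7 / 32, tolerance = 1e-3)
  expect_equal(unname(f$theta), c(0, 1), tolerance = 1e-6)
  expect_identical(sum(f$precise), 25L)
  expect_true(f$sigma > 50)  # errors were drawn with sd 92.6
  expect_true(f$sigma_defined)
})

test_that("all-exact responses give lambda zero with undefined sigma", {
  d <- recovery_data(lambda = 0, seed = 21)
  f <- pnp(response ~ cue_1 + cue_2 + cue_3 + cue_4, d)
  expect_identical(f$lambda, 0)
  expect_false(f$sigma_defined)
  expect_true(is.na(f$sigma))
  expect_true(all(f$precise))
  expect_equal(unname(f$theta), c(50, 4, 3, 2, 1), tolerance = 1e-9)
})

test_that("with no exact matches the mixture reduces to the Gaussian fit", {
  d <- make_fixture("id84_like", seed = 4)
  f <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-3)
  g <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-3, lambda = 1)
  expect_identical(f$lambda, 1)
  expect_equal(unname(f$theta), unname(g$theta), tolerance = 1e-9)
  expect_equal(f$sigma, g$sigma, tolerance = 1e-9)
  expect_identical(f$model, "pnp")
  expect_identical(g$model, "gaussian")
  expect_identical(g$k_free, f$k_free - 1L)
})

test_that("pure-noise fits match a dense lattice-search oracle", {
  # n = 20 trials, two algorithm parameters, homogeneous error
  d <- simulate_participant("expected_value", c(0, 1), lambda = 1,
                            sigma = 10, n = 20, cue_min = c(0.1, 10),
                            cue_max = c(0.8, 80), seed = 22)
  f <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-6)
  core <- d$cue_1 * d$cue_2
  oracle <- grid_oracle_loglik(d$response, core, tau = 1e-6,
                               a_grid = seq(-10, 10, by = 1),
                               b_grid = seq(0.5, 1.5, by = 0.05),
                               s_grid = c(5, 8, 10, 12, 15, 20))
  expect_gte(f$loglik, oracle)
  # and a separated instance where the oracle lattice contains the truth
  d2 <- simulate_participant("expected_value", c(0, 1), lambda = 0.3,
                             sigma = 10, n = 20, cue_min = c(0.1, 10),
                             cue_max = c(0.8, 80), seed = 23)
  f2 <- pnp(response ~ cue_1 + cue_2, d2, algorithm = "expected_value",
            tau = 1e-6)
  oracle2 <- grid_oracle_loglik(d2$response, d2$cue_1 * d2$cue_2, tau = 1e-6,
                                a_grid = c(-1, 0, 1),
                                b_grid = c(0.9, 1, 1.1),
                                s_grid = c(5, 10, 20))
  expect_gte(f2$loglik, oracle2)
})

test_that("separation identity: lambda is the share of separated trials", {
  # m of n responses deviate hugely relative to tau, the rest are exact
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    m <- sample(5:15, 1)
    C <- matrix(runif(2 * n, c(0.1, 10), c(0.8, 80)), n, 2, byrow = TRUE)
    theta_star <- c(2, 1.2)
    y <- theta_star[1] + theta_star[2] * C[, 1] * C[, 2]
    bad <- sample(n, m)
    y[bad] <- y[bad] + sample(c(-1, 1), m, TRUE) * runif(m, 30, 120)
    d <- data.frame(cue_1 = C[, 1], cue_2 = C[, 2], response = y)
    f <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
             tau = 1e-5)
    expect_equal(f$lambda, m / n, tolerance = 1e-6)
    expect_equal(unname(f$theta), theta_star, tolerance = 1e-8)
  }
})

test_that("the mixture log-likelihood dominates the Gaussian baseline", {
  for (seed in 1:6) {
    lam <- c(0, 0.2, 0.5, 0.8, 1, 0.35)[seed]
    d <- recovery_data(lambda = lam, seed = 100 + seed)
    fo <- response ~ cue_1 + cue_2 + cue_3 + cue_4
    f <- pnp(fo, d)
    g <- suppressWarnings(pnp(fo, d, lambda = 1))
    # evaluate the Gaussian solution under the mixture density
    g_under_mix <- if (g$sigma > f$tau)
      pnp_loglik(d$response, g$fitted.values, 1, g$sigma, f$tau) else -Inf
    expect_gte(f$loglik, g_under_mix)
  }
})

test_that("partial contamination shrinks the Gaussian error estimate", {
  d <- recovery_data(lambda = 0.5, seed = 30)
  fo <- response ~ cue_1 + cue_2 + cue_3 + cue_4
  f <- pnp(fo, d)
  g <- pnp(fo, d, lambda = 1)
  # half the trials are exact, so the homogeneous sd is pulled below the
  # true execution-error sd while the mixture estimates it from errors only
  expect_gt(g$sigma, 0)
  expect_lt(g$sigma, 10)
  expect_gt(f$sigma, g$sigma)
  expect_equal(f$sigma, 10, tolerance = 0.35)
})

test_that("degenerate and underdetermined inputs are flagged", {
  d <- recovery_data(lambda = 0, seed = 31)
  fo <- response ~ cue_1 + cue_2 + cue_3 + cue_4
  expect_warning(pnp(fo, d, lambda = 1), "degenerate")
  expect_error(pnp(fo, d[1:4, ]), "underdetermined")
  # constant responses with non-constant predictions
  d2 <- d
  d2$response <- rep(5, nrow(d))
  expect_warning(pnp(fo, d2), "degenerate")
})

test_that("fits are reproducible and leave the caller's RNG untouched", {
  d <- recovery_data(lambda = 0.6, seed = 32)
  fo <- response ~ cue_1 + cue_2 + cue_3 + cue_4
  set.seed(77)
  before <- .Random.seed
  f1 <- pnp(fo, d)
  expect_identical(.Random.seed, before)
  f2 <- pnp(fo, d)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$theta, f2$theta)
})

test_that("fit methods expose the standard modelling interface", {
  d <- make_fixture("id24_like", seed = 3)
  f <- pnp(response ~ cue_1 + cue_2, d, algorithm = "expected_value",
           tau = 1e-3)
  expect_named(coef(f), c("alpha", "beta"))
  ll <- logLik(f)
  expect_identical(attr(ll, "df"), f$k_free)
  expect_equal(BIC(ll), f$bic)
  expect_equal(predict(f), fitted(f))
  expect_equal(predict(f, d[3:5, ]), fitted(f)[3:5])
  expect_equal(residuals(f), d$response - fitted(f))
  s <- simulate(f, nsim = 2, seed = 5)
  expect_identical(dim(s), c(32L, 2L))
  expect_output(print(summary(f)), "precise trials: 25 / 32")
  js <- jsonlite::fromJSON(pnp_json(f))
  expect_named(js, c("theta", "sigma", "lambda", "tau", "loglik", "n",
                     "k_free", "bic", "adj_r2", "sigma_defined",
                     "precise_mask"))
  expect_length(js$precise_mask, 32L)
  expect_equal(js$lambda, f$lambda)
})
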