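test_that("linear-additive predictions are the weighted cue sums", {
  a <- pnp_algorithm("linear_additive", ncue = 4)
  th <- c(50, 4, 3, 2, 1)
  expect_equal(predict(a, matrix(0, 1, 4), th), 50)
  expect_equal(predict(a, matrix(10, 1, 4), th), 150)
  expect_equal(predict(a, matrix(c(1, 0, 0, 0), 1), c(0, 4, 3, 2, 1)), 4)
})

test_that("scaled reference functions apply alpha + beta * core", {
  expect_equal(predict(pnp_algorithm("area_scaled"), matrix(10), c(0, 1)), 10)
  # a plank .20 m wide and 20 m long covers 4 m^2
  expect_equal(predict(pnp_algorithm("product"), cbind(0.2, 20), c(0, 1)), 4)
  expect_equal(predict(pnp_algorithm("dividend_m1"), cbind(4, 20), c(0, 1)),
               0.2)
  expect_equal(predict(pnp_algorithm("dividend_m2"), cbind(4, 0.2), c(0, 1)),
               20)
  # an overweighted expected value: 1.61 * (.5 * 100)
  expect_equal(predict(pnp_algorithm("expected_value"), cbind(0.5, 100),
                       c(0, 1.61)), 80.5)
  expect_error(predict(pnp_algorithm("dividend_m1"), cbind(c(4, 4), c(20, 0)),
                       c(0, 1)), "zero divisor.*2")
})

test_that("the nonadditive exponential criterion matches its closed form", {
  na <- pnp_algorithm("nonadditive_exp")
  expect_equal(predict(na, matrix(0, 1, 4)), 509.05 + 0.54)
  expect_equal(predict(na, matrix(10, 1, 4)), 509.05 + 0.54 * exp(100 / 18))
  expect_identical(na$npar, 0L)
  # strictly increasing in every cue
  set.seed(11)
  for (r in 1:20) {
    x <- runif(4, 0, 10)
    j <- sample(4, 1)
    x2 <- x
    x2[j] <- x[j] + runif(1, 0.1, 3)
    expect_gt(predict(na, matrix(x2, 1)), predict(na, matrix(x, 1)))
  }
})

test_that("exemplar predictions are similarity-weighted criterion averages", {
  E1 <- matrix(c(1, 2, 3, 4), 1)
  one <- pnp_algorithm("exemplar", exemplars = E1, criteria = 42)
  for (dl in c(0, 1, 50))
    expect_equal(predict(one, matrix(9, 1, 4), c(dl, rep(0.25, 4))), 42)

  set.seed(12)
  E <- matrix(runif(12, 0, 10), 3, 4)
  crit <- c(10, 20, 60)
  ex <- pnp_algorithm("exemplar", exemplars = E, criteria = crit)
  probe <- matrix(c(2, 5, 1, 7), 1)
  # delta = 0: all similarities are 1, so the unweighted mean
  expect_equal(predict(ex, probe, c(0, rep(0.25, 4))), mean(crit))
  # manual summation oracle at delta = 1, unit attention weights
  w <- exp(-1 * colSums(abs(t(E) - as.numeric(probe)) * 1))
  expect_equal(predict(ex, probe, c(1, rep(1, 4))),
               sum(w * crit) / sum(w))
})

test_that("exemplar predictions stay convex and reach the nearest exemplar", {
  set.seed(13)
  E <- matrix(runif(40, 0, 10), 10, 4)
  crit <- runif(10, 100, 900)
  ex <- pnp_algorithm("exemplar", exemplars = E, criteria = crit)
  for (r in 1:25) {
    probe <- matrix(runif(4, -5, 15), 1)
    th <- c(runif(1, 0, 3), runif(4, 0, 1))
    p <- predict(ex, probe, th)
    expect_gte(p, min(crit))
    expect_lte(p, max(crit))
  }
  # delta -> large converges to the single nearest exemplar's criterion
  probe <- E[4, , drop = FALSE] + 0.01
  expect_equal(predict(ex, probe, c(40, rep(1, 4))), crit[4],
               tolerance = 1e-6)
  # full underflow falls back to the unweighted mean, flagged
  far <- matrix(1e6, 1, 4)
  p <- predict(ex, far, c(10, rep(1, 4)))
  expect_equal(as.numeric(p), mean(crit))
  expect_identical(attr(p, "underflow"), 1L)
})

test_that("exact solves invert noise-free minimal subsets", {
  # two consistent (EV, y) pairs determine the line uniquely
  th <- exact_solve("expected_value", cbind(c(0.5, 0.2), c(100, 50)),
                    c(0 + 1.5 * 50, 0 + 1.5 * 10))
  expect_equal(unname(th), c(0, 1.5), tolerance = 1e-9)
  # duplicated trials make the subset singular
  expect_null(exact_solve("expected_value", cbind(c(0.5, 0.5), c(100, 100)),
                          c(75, 75)))
  # five noise-free trials of the additive rule recover theta exactly
  set.seed(14)
  C <- matrix(runif(20, 0, 10), 5, 4)
  truth <- c(50, 4, 3, 2, 1)
  y <- drop(cbind(1, C) %*% truth)
  expect_equal(unname(exact_solve("linear_additive", C, y)), truth,
               tolerance = 1e-9)
  # solve o predict is the identity on theta (conditioned random subsets)
  for (r in 1:10) {
    C <- matrix(runif(20, 0, 10), 5, 4)
    th0 <- c(rnorm(1, 0, 20), rnorm(4, 0, 3))
    y <- drop(cbind(1, C) %*% th0)
    th1 <- exact_solve("linear_additive", C, y)
    if (!is.null(th1)) expect_equal(unname(th1), th0, tolerance = 1e-7)
  }
})

test_that("algorithm construction validates its inputs", {
  expect_error(pnp_algorithm("exemplar"), "requires")
  expect_error(pnp_algorithm("exemplar", exemplars = matrix(1, 2, 2),
                             criteria = 1), "one value per exemplar")
  expect_error(predict(pnp_algorithm("product"), matrix(1, 1, 3), c(0, 1)),
               "expects 2 cue")
  expect_error(predict(pnp_algorithm("product"), cbind(1, 2), c(0, 1, 2)),
               "parameter")
})
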