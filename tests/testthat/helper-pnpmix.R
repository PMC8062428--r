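# shared fixtures and independent oracles, built in code at test time

# one participant of the recovery design (linear-additive truth)
recovery_data <- function(lambda, n = 50, seed = 1,
                          theta = c(50, 4, 3, 2, 1), sigma = 10) {
  simulate_participant("linear_additive", theta, lambda, sigma, n = n,
                       seed = seed)
}

# brute-force lattice search over (lambda, alpha, beta, sigma) for a
# two-parameter scaled algorithm; independent of the fitting path
grid_oracle_loglik <- function(y, core, tau,
                               lam_grid = seq(0, 1, by = 0.1),
                               a_grid, b_grid, s_grid) {
  best <- -Inf
  for (lam in lam_grid) {
    for (a in a_grid) {
      for (b in b_grid) {
        pred <- a + b * core
        if (lam == 0) {
          ll <- pnp_loglik(y, pred, 0, NA, tau)
          best <- max(best, ll)
        } else {
          for (s in s_grid) {
            if (s <= tau) next
            best <- max(best, pnp_loglik(y, pred, lam, s, tau))
          }
        }
      }
    }
  }
  best
}

# minimal stand-in for a classified participant, for summary-rule tests
mock_selection <- function(best = "linear_additive", lambda = 0.5,
                           sigma = 8, sigma_defined = TRUE, adj_r2 = 0.9,
                           si = NA_real_, theta = c(alpha = 0, beta = 1)) {
  fit <- list(lambda = lambda, sigma = sigma, sigma_defined = sigma_defined,
              adj_r2 = adj_r2, theta = theta)
  out <- list(best = best, fit = fit, label = lambda_label(lambda), si = si)
  class(out) <- "pnp_select"
  out
}
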