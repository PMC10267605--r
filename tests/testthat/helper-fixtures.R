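# shared fixtures: built in code, no files

# the strongly right-skewed TSH-like healthy model used across tests
tsh_model <- function() box_cox_gaussian(lambda = 0.07, mu = 0.734424, sigma = 0.688931)

# plain Gaussian series (lambda = 1 shifts by 1 in original units)
gaussian_series <- function(n = 1e4, mu = 99, sigma = 10, seed = 42, decimals = 2L) {
  generate_lab_data(synthetic_spec(
    box_cox_gaussian(1, mu, sigma), n = n, decimals = decimals, seed = seed
  ))
}

rel_dev <- function(est, truth) (est - truth) / truth

# brute-force truncated-Gaussian likelihood over a (mu, sigma) grid;
# independent oracle for the quasi-Newton fit
trunc_loglik_grid <- function(y, t1y, t2y, mu_grid, sigma_grid) {
  inside <- y[y >= t1y & y <= t2y]
  ll <- function(mu, sigma) {
    Z <- pnorm((t2y - mu) / sigma) - pnorm((t1y - mu) / sigma)
    sum(dnorm(inside, mu, sigma, log = TRUE)) - length(inside) * log(Z)
  }
  g <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  g$loglik <- mapply(ll, g$mu, g$sigma)
  g[which.max(g$loglik), ]
}

# naive sup-distance between the renormalised empirical CDF of insiders and
# the truncated-Gaussian CDF, evaluated observation by observation
ks_truncated_naive <- function(y, mu, sigma, t1y, t2y) {
  inside <- sort(y[y >= t1y & y <= t2y])
  k <- length(inside)
  A <- pnorm((t1y - mu) / sigma); B <- pnorm((t2y - mu) / sigma)
  Fm <- (pnorm((inside - mu) / sigma) - A) / (B - A)
  Fe_hi <- seq_len(k) / k
  Fe_lo <- (seq_len(k) - 1) / k
  max(abs(Fe_hi - Fm), abs(Fe_lo - Fm))
}

# fast kosmic settings for unit tests (coarser grids, same algorithm)
kosmic_config_fast <- function(..., tolerance = 1e-3) {
  kosmic_config(q_step = 0.05, lambda_grid = seq(0, 1, by = 0.25),
                tolerance = tolerance, ...)
}
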