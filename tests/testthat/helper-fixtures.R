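# Shared fixtures: everything is generated in code at test time.

# one small simulated dataset
tiny_sim <- function(scenario = "one_dim", n = 80, seed = 42) {
  simulate_scenario(scenario, n = n, D = 1, seed = seed)[[1]]
}

quick_config <- function(...) {
  sampler_config(n_chains = 2, burn_in = 200, retained = 200, seed = 9, ...)
}

# independent reference sampler for the conjugate reduction check: scalar
# random-walk Metropolis for a logistic regression slope with fixed offset
# and a N(0, sigma^2) prior — deliberately naive and separate from the
# package's C++ path.
reference_theta_mh <- function(y, x, offset, sigma = 1, iters = 40000,
                               step = 0.3, theta0 = 0) {
  logpost <- function(th) {
    eta <- offset + th * x
    sum(y * eta - log1p(exp(eta))) - th^2 / (2 * sigma^2)
  }
  th <- theta0
  lp <- logpost(th)
  out <- numeric(iters)
  for (i in seq_len(iters)) {
    prop <- th + step * rnorm(1)
    lpp <- logpost(prop)
    if (log(runif(1)) < lpp - lp) {
      th <- prop
      lp <- lpp
    }
    out[i] <- th
  }
  out[-seq_len(iters %/% 4)]
}

# brute-force Matern correlation matrix (double loop oracle)
brute_force_corr <- function(locations, rho, jitter) {
  n <- nrow(locations)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      d <- sqrt(sum((locations[j, ] - locations[k, ])^2))
      M[j, k] <- (1 + d / rho) * exp(-d / rho)
    }
  }
  diag(M) <- 1 + jitter
  M
}
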