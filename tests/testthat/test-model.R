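test_that("quantile scoring matches the closed cases and a rank oracle", {
  expect_equal(drop(quantize_components(matrix(1:4), q = 4)), 0:3)
  expect_equal(drop(quantize_components(matrix(c(10, 10, 20, 20)), q = 2)),
    c(0, 0, 1, 1))

  set.seed(10)
  x <- rnorm(1000)
  s <- drop(quantize_components(matrix(x), q = 4))
  expect_equal(unname(table(s)), rep(250, 4), ignore_attr = TRUE)
  # rank-based oracle on the same draws (distinct values)
  oracle <- ceiling(rank(x) / 250) - 1
  expect_equal(s, oracle)
})

test_that("quantile scores are invariant to strictly monotone transforms", {
  set.seed(11)
  x <- matrix(rlnorm(600), ncol = 3)
  expect_identical(quantize_components(x, q = 4), quantize_components(exp(x), q = 4))
  expect_identical(quantize_components(x, q = 5), quantize_components(x * 100 + 7, q = 5))
})

test_that("constant columns are rejected by name", {
  x <- cbind(a = rnorm(20), b = rep(2, 20))
  expect_error(quantize_components(x, q = 4), "b", class = "svcmix_degenerate_column")
})

test_that("group index is the weighted score sum and is monotone", {
  expect_equal(group_index(c(2, 0, 1), c(1, 0, 0)), 2)
  w <- c(0.2, 0.5, 0.3)
  expect_equal(group_index(c(3, 3, 3), w), 3)
  omega1 <- c(0.30, 0.20, 0.20, 0.13, 0.10, 0.07)
  expect_equal(group_index(c(3, 2, 1, 0, 3, 3), omega1), 2.01, tolerance = 1e-12)
  # monotone nondecreasing in every score entry
  set.seed(12)
  for (rep in 1:20) {
    q <- sample(0:3, 6, replace = TRUE)
    k <- sample(6, 1)
    q2 <- q; q2[k] <- q2[k] + 1
    expect_gte(group_index(q2, omega1), group_index(q, omega1))
  }
  expect_error(group_index(c(1, 2), c(0.7, 0.7)), class = "svcmix_invalid_parameter")
})

make_params <- function(n, C, rho = 0.5, theta = numeric(0)) {
  svcmix_params(
    beta0 = rnorm(n), beta = matrix(rnorm(n * C), n),
    omega = replicate(C, {
      w <- rexp(4)
      w / sum(w)
    }, simplify = FALSE),
    theta = theta, rho = rho, tau_beta = rep(1.3, C + 1),
    sigma_theta = rep(1, length(theta))
  )
}

test_that("vectorized linear predictor equals the per-subject loop", {
  set.seed(13)
  n <- 25; C <- 2; B <- 2
  p <- make_params(n, C, theta = rnorm(B))
  quantized <- replicate(C, matrix(sample(0:3, n * 4, TRUE), n), simplify = FALSE)
  X <- matrix(rnorm(n * B), n)
  eta <- linear_predictor(p, quantized, X)
  loop <- vapply(seq_len(n), function(i) {
    e <- p$beta0[i]
    for (j in seq_len(C)) e <- e + p$beta[i, j] * sum(quantized[[j]][i, ] * p$omega[[j]])
    e + sum(p$theta * X[i, ])
  }, numeric(1))
  expect_equal(eta, loop, tolerance = 1e-12)

  p0 <- make_params(n, C)
  p0$beta0[] <- 0; p0$beta[] <- 0
  expect_equal(linear_predictor(p0, quantized), rep(0, n))
})

test_that("log likelihood matches closed forms and a naive sum", {
  n <- 4
  p <- svcmix_params(beta0 = rep(0, n), beta = matrix(0, n, 1),
    omega = list(c(0.5, 0.5)), rho = 1, tau_beta = c(1, 1))
  qz <- list(matrix(0, n, 2))
  expect_equal(log_likelihood(p, rep(1, n), qz), -4 * log(2), tolerance = 1e-12)
  expect_equal(log_likelihood(p, c(0, 1, 0, 1), qz), -4 * log(2), tolerance = 1e-12)

  # one observation, Y = 1, eta = log 3 -> log(3/4)
  p1 <- svcmix_params(beta0 = log(3), beta = matrix(0, 1, 1),
    omega = list(c(1)), rho = 1, tau_beta = c(1, 1))
  expect_equal(log_likelihood(p1, 1, list(matrix(0, 1, 1))), log(0.75),
    tolerance = 1e-12)

  set.seed(14)
  n <- 40
  p <- make_params(n, 2, theta = rnorm(2))
  quantized <- replicate(2, matrix(sample(0:3, n * 4, TRUE), n), simplify = FALSE)
  X <- matrix(rnorm(n * 2), n)
  y <- rbinom(n, 1, 0.5)
  eta <- linear_predictor(p, quantized, X)
  naive <- sum(y * log(plogis(eta)) + (1 - y) * log(1 - plogis(eta)))
  expect_equal(log_likelihood(p, y, quantized, X), naive, tolerance = 1e-10)
})

test_that("Bernoulli log likelihood is concave in the linear predictor", {
  y <- c(1, 0, 1, 1, 0)
  v <- c(0.5, -1, 2, 0.3, 1.4)
  f <- function(t) sum(y * (t * v) - log1p(exp(t * v)))
  ts <- seq(-3, 3, by = 0.25)
  vals <- vapply(ts, f, numeric(1))
  second_diff <- diff(diff(vals))
  expect_true(all(second_diff <= 1e-10))
})

test_that("log prior agrees with textbook densities and respects support", {
  design <- mixture_design(list(mix1 = paste0("c", 1:3)))
  priors <- prior_spec(rho_bounds = c(0.1, 1))

  # outside the range support
  p <- svcmix_params(beta0 = 0, beta = matrix(0.2, 1, 1), omega = list(rep(1 / 3, 3)),
    rho = 5, tau_beta = c(1, 1))
  expect_identical(log_prior(p, priors, matrix(c(0.5, 0.5), 1), design), -Inf)

  # single location, tau = 1: each field term reduces to a standard normal,
  # plus the Dirichlet normalizer log((C-1)!) for the uniform simplex and the
  # uniform densities for rho and the two field scales
  p$rho <- 0.5
  lp <- log_prior(p, priors, matrix(c(0.5, 0.5), 1), design, jitter = 0)
  manual <- dnorm(0, log = TRUE) + dnorm(0.2, log = TRUE) +
    lgamma(3) - log(1 - 0.1) - 2 * log(10)
  expect_equal(lp, manual, tolerance = 1e-9)
})

test_that("log prior multivariate field term matches an independent MVN oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(15)
  n <- 8
  locs <- cbind(runif(n), runif(n))
  design <- mixture_design(list(mix1 = paste0("c", 1:4)))
  priors <- prior_spec(rho_bounds = c(0.05, 2))
  tau <- c(2.5, 0.7)
  p <- svcmix_params(beta0 = rnorm(n), beta = matrix(rnorm(n), n, 1),
    omega = list(c(0.4, 0.3, 0.2, 0.1)), rho = 0.6, tau_beta = tau)
  Omega <- matern_correlation_matrix(locs, 0.6, jitter = 1e-6)
  oracle <- mvtnorm::dmvnorm(p$beta0, sigma = Omega / tau[1], log = TRUE) +
    mvtnorm::dmvnorm(p$beta[, 1], sigma = Omega / tau[2], log = TRUE) +
    (lgamma(4) + sum((1 - 1) * log(p$omega[[1]]))) -
    log(2 - 0.05) - 2 * log(10)
  expect_equal(log_prior(p, priors, locs, design), oracle, tolerance = 1e-8)
})

test_that("log posterior is additive and permutation invariant", {
  set.seed(16)
  sim <- tiny_sim(n = 30, seed = 8)
  data <- mixture_data(sim$data, sim$design)
  qz <- quantize_components(data)
  priors <- prior_spec(rho_bounds = unname(pairwise_distance_bounds(data$locations)))
  n <- data$n
  p <- svcmix_params(beta0 = rnorm(n), beta = matrix(rnorm(n), n, 1),
    omega = list(rep(1 / 6, 6)), rho = 0.5, tau_beta = c(1, 2))
  lp <- log_posterior(p, data, qz, priors)
  expect_equal(lp,
    log_prior(p, priors, data$locations, data$design) +
      log_likelihood(p, data$outcome, qz),
    tolerance = 1e-10)

  # shuffle subjects consistently: the joint density is exchangeable
  perm <- sample(n)
  data2 <- data
  data2$locations <- data$locations[perm, ]
  data2$outcome <- data$outcome[perm]
  data2$components <- lapply(data$components, function(m) m[perm, ])
  qz2 <- quantize_components(data2)
  p2 <- p
  p2$beta0 <- p$beta0[perm]
  p2$beta <- p$beta[perm, , drop = FALSE]
  expect_equal(log_posterior(p2, data2, qz2, priors), lp, tolerance = 1e-8)

  # support violations propagate as -Inf, not errors
  p$rho <- 99
  expect_identical(log_posterior(p, data, qz, priors), -Inf)
})

test_that("dataset validation rejects malformed inputs", {
  sim <- tiny_sim(n = 20, seed = 3)
  expect_s3_class(mixture_data(sim$data, sim$design), "svcmix_data")
  bad <- sim$data
  bad$outcome[3] <- 2
  expect_error(mixture_data(bad, sim$design), "binary")
  bad2 <- sim$data
  bad2$mix1_c2[5] <- NA
  expect_error(mixture_data(bad2, sim$design), "Missing")
  expect_error(mixture_data(sim$data[, -2], sim$design), "not found")
})
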