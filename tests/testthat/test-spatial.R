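test_that("Matern-3/2 correlation matches its closed form and decays", {
  expect_identical(matern32_correlation(0, rho = 0.3), 1)
  expect_equal(matern32_correlation(0.3, rho = 0.3), 2 * exp(-1), tolerance = 1e-12)
  expect_equal(matern32_correlation(3, rho = 0.3), 11 * exp(-10), tolerance = 1e-12)
  expect_equal(matern32_correlation(0.3, rho = 0.3), 0.735759, tolerance = 1e-6)

  d <- seq(0, 5, by = 0.01)
  r <- matern32_correlation(d, rho = 0.7)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r > 0 & r <= 1))

  expect_error(matern32_correlation(1, rho = 0), class = "svcmix_invalid_parameter")
  expect_error(matern32_correlation(-1, rho = 1), class = "svcmix_invalid_parameter")
})

test_that("correlation matrix equals a brute-force double loop", {
  set.seed(1)
  locs <- cbind(runif(40), runif(40))
  for (rho in c(0.05, 0.4, 2)) {
    expect_equal(matern_correlation_matrix(locs, rho, jitter = 1e-6),
      brute_force_corr(locs, rho, 1e-6),
      tolerance = 1e-12)
  }
})

test_that("correlation matrix handles degenerate geometries", {
  expect_equal(matern_correlation_matrix(cbind(0.3, 0.4), 0.5, jitter = 1e-4),
    matrix(1 + 1e-4), tolerance = 1e-12)
  # two locations exactly one range apart
  locs2 <- rbind(c(0, 0), c(0.3, 0))
  M <- matern_correlation_matrix(locs2, rho = 0.3, jitter = 0)
  expect_equal(M[1, 2], 0.735759, tolerance = 1e-6)
  # rho -> 0+ gives a near-identity matrix
  M0 <- matern_correlation_matrix(locs2, rho = 1e-4, jitter = 0)
  expect_lt(M0[1, 2], 1e-10)
  # coincident points demand jitter
  expect_error(
    matern_correlation_matrix(rbind(c(1, 1), c(1, 1)), 0.3, jitter = 0),
    class = "svcmix_singular_geometry"
  )
})

test_that("pairwise distance bounds bracket every pairwise distance", {
  expect_equal(unname(pairwise_distance_bounds(rbind(c(0, 0), c(1, 1)))),
    c(sqrt(2), sqrt(2)))
  expect_equal(unname(pairwise_distance_bounds(rbind(c(0, 0), c(0, 1), c(0, 3)))),
    c(1, 3))
  set.seed(2)
  locs <- cbind(runif(100), runif(100))
  b <- pairwise_distance_bounds(locs)
  d <- as.numeric(dist(locs))
  expect_true(all(d >= b[1] - 1e-12 & d <= b[2] + 1e-12))
  expect_error(pairwise_distance_bounds(rbind(c(1, 2), c(1, 2))),
    class = "svcmix_degenerate_geometry")
})

test_that("conditional draws interpolate exactly at the observed sites", {
  set.seed(3)
  locs <- cbind(runif(12), runif(12))
  f <- rnorm(12)
  draw <- conditional_field_draw(f, locs, locs, rho = 0.4, tau = 2, jitter = 0)
  expect_equal(draw, f, tolerance = 1e-8)
})

test_that("a far-away point reverts to the prior marginal", {
  set.seed(4)
  obs <- cbind(runif(5, 0, 0.01), runif(5, 0, 0.01))
  f <- rnorm(5)
  far <- matrix(c(50, 50), 1)
  tau <- 4
  draws <- replicate(10000,
    conditional_field_draw(f, obs, far, rho = 0.05, tau = tau))
  expect_equal(mean(draws), 0, tolerance = 4 * sqrt(1 / tau / 10000) * 3)
  expect_equal(var(draws), 1 / tau, tolerance = 0.02)
})

test_that("2x2 MVN conditioning gives mean r(d) * f_obs", {
  d <- 0.25
  rho <- 0.4
  r <- matern32_correlation(d, rho)
  f_obs <- 1.7
  set.seed(5)
  draws <- replicate(20000, conditional_field_draw(
    f_obs, matrix(c(0, 0), 1), matrix(c(d, 0), 1), rho = rho, tau = 1, jitter = 0))
  cond_sd <- sqrt(1 - r^2)
  expect_equal(mean(draws), r * f_obs, tolerance = 4 * cond_sd / sqrt(20000) * 3)
  expect_equal(sd(draws), cond_sd, tolerance = 0.02)
})

test_that("empirical covariance of conditional draws matches the analytic one", {
  set.seed(6)
  obs <- cbind(runif(4), runif(4))
  new <- cbind(runif(3), runif(3))
  f <- rnorm(4)
  rho <- 0.5; tau <- 2; jit <- 1e-8
  draws <- t(replicate(100000, conditional_field_draw(f, obs, new, rho, tau, jit)))
  # analytic conditional covariance
  S_oo <- matern_correlation_matrix(obs, rho, jit)
  D_no <- sqrt(outer(new[, 1], obs[, 1], "-")^2 + outer(new[, 2], obs[, 2], "-")^2)
  S_no <- matrix(matern32_correlation(D_no, rho), nrow(new))
  S_nn <- matern_correlation_matrix(new, rho, jit)
  cond <- (S_nn - S_no %*% solve(S_oo) %*% t(S_no)) / tau
  expect_equal(cov(draws), cond, tolerance = 0.02)
  expect_equal(colMeans(draws), drop(S_no %*% solve(S_oo, f)), tolerance = 0.02)
})

test_that("compiled grid-draw kernel agrees with the R conditioning path", {
  set.seed(7)
  obs <- cbind(runif(15), runif(15))
  new <- cbind(runif(6), runif(6))
  f <- rnorm(15)
  rho <- 0.3; tau <- 1.5; jit <- 1e-6
  set.seed(11)
  r_draw <- conditional_field_draw(f, obs, new, rho, tau, jit)
  D_oo <- as.matrix(dist(obs))
  D_no <- sqrt(outer(new[, 1], obs[, 1], "-")^2 + outer(new[, 2], obs[, 2], "-")^2)
  D_nn <- as.matrix(dist(new))
  set.seed(11)
  c_draw <- svcmix:::.svm_grid_draws(matrix(f, 1), rho, tau, D_oo, D_no, D_nn, jit)
  expect_equal(drop(c_draw), r_draw, tolerance = 1e-8)
})

test_that("grid centers tile the bounding box", {
  g <- grid_centers(30)
  expect_equal(nrow(g), 900)
  expect_equal(min(g$x), 1 / 60)
  expect_equal(max(g$y), 1 - 1 / 60)
  g2 <- grid_centers(5, bbox = c(0, 2, 1, 3))
  expect_equal(range(g2$x), c(0.2, 1.8))
  expect_equal(range(g2$y), c(1.2, 2.8))
})
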