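test_that("true mean surfaces follow the scenario geometry", {
  od <- surface_spec("one_dim")
  expect_equal(true_mean_surface(od, cbind(0.1, 0.5)), 3)
  expect_equal(true_mean_surface(od, cbind(0.5, 0.9)), 1.5)
  expect_equal(true_mean_surface(od, cbind(0.9, 0.1)), 0)
  # band boundaries are right-open: x = 1/3 belongs to the middle band
  expect_equal(true_mean_surface(od, cbind(1 / 3, 0.5)), 1.5)

  rad <- surface_spec("radial")
  expect_equal(true_mean_surface(rad, cbind(0.5, 0.5)), 3)
  expect_equal(true_mean_surface(rad, cbind(0.5, 1.0)), 0)
  expect_equal(true_mean_surface(rad, cbind(0.5, 0.75)), 1.5)
  expect_equal(true_mean_surface(rad, cbind(0.05, 0.05)), 0) # clamped corner

  expect_equal(true_mean_surface(surface_spec("constant", constant_mean = 1),
    cbind(0.2, 0.8)), 1)
})

test_that("locations are uniform on the unit square and reproducible", {
  l1 <- sample_locations(10000, seed = 41)
  l2 <- sample_locations(10000, seed = 41)
  expect_identical(l1, l2)
  expect_true(all(l1 > 0 & l1 < 1))
  se3 <- 3 * sqrt(1 / 12 / 10000)
  expect_equal(unname(colMeans(l1)), c(0.5, 0.5), tolerance = se3 * 2)
})

test_that("components reproduce the preset correlation structure", {
  R1 <- preset_correlation(1)
  expect_true(isSymmetric(R1))
  expect_equal(R1[1, 2], 0.3)
  expect_equal(preset_correlation(2)[1, 2], 0.2)
  x <- sample_components(100000, R1, seed = 42)
  emp <- cor(x)
  expect_equal(emp[1, 2], 0.3, tolerance = 0.01)
  expect_equal(emp[3, 4], 0.1, tolerance = 0.01)
  # components 5 and 6 are uncorrelated with everything else
  expect_lt(max(abs(emp[5:6, 1:4])), 0.01)
  expect_lt(abs(emp[5, 6]), 0.01)

  xid <- sample_components(100000, diag(4), seed = 43)
  cid <- cor(xid)
  expect_lt(max(abs(cid[upper.tri(cid)])), 0.01)
  expect_error(sample_components(10, matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("true effects are the mean surface plus SD-0.1 noise", {
  spec <- surface_spec("one_dim", sd = 0)
  locs <- sample_locations(200, seed = 44)
  expect_equal(sample_effects(spec, locs), true_mean_surface(spec, locs))

  spec1 <- surface_spec("one_dim", sd = 0.1)
  locs <- sample_locations(10000, seed = 45)
  eff <- sample_effects(spec1, locs, seed = 46)
  resid <- eff - true_mean_surface(spec1, locs)
  expect_equal(sd(resid), 0.1, tolerance = 0.005)
  band <- cut(locs[, 1], c(0, 1 / 3, 2 / 3, 1), labels = FALSE)
  means <- tapply(eff, band, mean)
  se3 <- 3 * 0.1 / sqrt(min(table(band)))
  expect_equal(as.numeric(means), c(3, 1.5, 0), tolerance = se3 * 2)
})

test_that("intercept calibration hits a 1:1 case:control ratio", {
  set.seed(47)
  n <- 5000
  qz <- list(matrix(sample(0:3, n * 6, TRUE), n))
  w <- list(c(0.30, 0.20, 0.20, 0.13, 0.10, 0.07))

  # all effects zero: symmetric, so b0 = 0
  b00 <- calibrate_intercept(matrix(0, n, 1), w, qz)
  expect_equal(b00, 0, tolerance = 1e-7)

  eff <- matrix(rnorm(n, 2, 0.5), n, 1)
  b0 <- calibrate_intercept(eff, w, qz)
  expect_lt(b0, 0) # positive effects with nonnegative indices push b0 down
  p <- plogis(b0 + eff[, 1] * group_index(qz[[1]], w[[1]]))
  expect_equal(mean(p), 0.5, tolerance = 1e-7)
  # monotonicity of the expected case fraction in b0
  expect_gt(mean(plogis(b0 + 1 + eff[, 1] * group_index(qz[[1]], w[[1]]))), 0.5)

  y <- simulate_outcomes(eff, w, qz, b0, seed = 48)
  expect_true(all(y %in% c(0L, 1L)))
  expect_equal(mean(y), 0.5, tolerance = 3 * sqrt(0.25 / n))
  expect_identical(y, simulate_outcomes(eff, w, qz, b0, seed = 48))
  # overwhelming effects force all cases
  expect_true(all(simulate_outcomes(matrix(50, n, 1), w, qz, 5, seed = 49)[
    group_index(qz[[1]], w[[1]]) > 0] == 1L))
})

test_that("scenario presets embed the study design", {
  for (sc in c("constant_null", "one_dim", "radial", "two_mix_one_dim",
               "two_mix_radial")) {
    spec <- scenario_spec(sc)
    for (mx in spec$mixtures) {
      expect_equal(sum(mx$omega), 1, tolerance = 1e-12)
      expect_true(all(eigen(mx$corr, symmetric = TRUE)$values > 0))
    }
  }
  expect_equal(scenario_spec("one_dim")$mixtures$mix1$omega,
    c(0.30, 0.20, 0.20, 0.13, 0.10, 0.07))
  tm <- scenario_spec("two_mix_radial")
  expect_equal(tm$mixtures$mix2$omega, c(0.45, 0.15, 0.15, 0.15, 0.05, 0.05))
  expect_equal(tm$mixtures$mix2$surface$pattern, "constant")
  expect_equal(tm$mixtures$mix2$surface$constant_mean, 1)
  expect_equal(tm$mixtures$mix1$surface$pattern, "radial")
})

test_that("scenario generation is reproducible with distinct datasets", {
  s1 <- simulate_scenario("one_dim", n = 60, D = 3, seed = 5)
  s2 <- simulate_scenario("one_dim", n = 60, D = 3, seed = 5)
  expect_identical(s1, s2)
  outs <- lapply(s1, function(d) d$data$outcome)
  expect_false(identical(outs[[1]], outs[[2]]))
  expect_false(identical(outs[[2]], outs[[3]]))
  # truth rows align with data rows
  expect_identical(s1[[1]]$data$x, s1[[1]]$truth$x)
  expect_equal(ncol(s1[[1]]$data), 4 + 6)
  # roughly balanced cases and controls
  expect_lt(abs(mean(s1[[1]]$data$outcome) - 0.5), 0.2)
})
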