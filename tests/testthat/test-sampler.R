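test_that("identical seeds reproduce draws bit for bit", {
  sim <- tiny_sim(n = 30, seed = 21)
  cfg <- sampler_config(n_chains = 2, burn_in = 100, retained = 100, seed = 7)
  f1 <- suppressWarnings(svcmix(sim$data, sim$design$mixtures, config = cfg))
  f2 <- suppressWarnings(svcmix(sim$data, sim$design$mixtures, config = cfg))
  expect_identical(f1$chains$chain1$rho, f2$chains$chain1$rho)
  expect_identical(f1$chains$chain2$omega[[1]], f2$chains$chain2$omega[[1]])
  expect_identical(f1$chains$chain1$beta[[1]], f2$chains$chain1$beta[[1]])
  # different seed differs
  cfg$seed <- 8L
  f3 <- suppressWarnings(svcmix(sim$data, sim$design$mixtures, config = cfg))
  expect_false(identical(f1$chains$chain1$rho, f3$chains$chain1$rho))
})

test_that("prior-only runs recover the Dirichlet and uniform priors", {
  sim <- tiny_sim(n = 25, seed = 22)
  cfg <- sampler_config(n_chains = 1, burn_in = 500, retained = 10000,
    seed = 3, likelihood = FALSE, store_fields = FALSE)
  fit <- svcmix(sim$data, sim$design$mixtures, config = cfg)
  om <- fit$chains$chain1$omega[[1]]
  C <- ncol(om)
  # Dirichlet(1) moments: mean 1/C, var (C-1)/(C^2 (C+1))
  expect_equal(unname(colMeans(om)), rep(1 / C, C), tolerance = 0.05)
  expect_equal(unname(apply(om, 2, var)), rep((C - 1) / (C^2 * (C + 1)), C),
    tolerance = 0.15)
  # rho uniform over the inter-point distance bounds (KS distance, thinned)
  rho <- fit$chains$chain1$rho[seq(1, 10000, by = 5)]
  rb <- fit$rho_bounds
  ks <- suppressWarnings(stats::ks.test(rho, "punif", rb[1], rb[2]))
  expect_lt(unname(ks$statistic), 0.06)
  expect_true(all(rho >= rb[1] & rho <= rb[2]))
  # field scales uniform on (0, 10)
  sb <- fit$chains$chain1$sigma_beta[, 2]
  expect_equal(mean(sb), 5, tolerance = 0.5)
})

test_that("Gelman-Rubin statistic follows the classic formula", {
  set.seed(23)
  a <- rnorm(10000)
  expect_equal(gelman_rubin(cbind(a, a)), sqrt(9999 / 10000), tolerance = 1e-12)
  expect_equal(gelman_rubin(cbind(rnorm(10000), rnorm(10000))), 1, tolerance = 0.01)
  # widely separated chains blow up the diagnostic
  expect_gt(gelman_rubin(cbind(rnorm(100), rnorm(100, 100))), 10)
  # identical repeating chains: B = 0 so PSRF = sqrt((n-1)/n) < 1
  ch <- rep(1:3, 4)
  expect_equal(gelman_rubin(cbind(ch, ch)), sqrt(11 / 12), tolerance = 1e-12)
  # hand check of the formula on asymmetric chains
  c1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  c2 <- c1 + 2
  n <- 10
  W <- (var(c1) + var(c2)) / 2
  B <- n * var(c(mean(c1), mean(c2)))
  expect_equal(gelman_rubin(cbind(c1, c2)), sqrt((n - 1) / n + B / (n * W)),
    tolerance = 1e-12)
  # degenerate: zero within-chain variance is an undefined diagnostic
  expect_true(is.na(gelman_rubin(cbind(rep(1, 20), rep(1, 20)))))
  expect_error(gelman_rubin(matrix(1:20, ncol = 1)), "two chains")
})

test_that("theta-only sampling matches an independent reference sampler", {
  set.seed(24)
  n <- 120
  xcov <- rnorm(n)
  offset <- rnorm(n, 0, 0.3)
  theta_true <- 0.8
  yobs <- rbinom(n, 1, plogis(offset + theta_true * xcov))

  # package path: fields and weights frozen at the truth, only theta moves
  df <- data.frame(
    id = 1:n, x = runif(n), y = runif(n), outcome = yobs,
    mix1_c1 = rnorm(n), cov1 = xcov
  )
  cfg <- sampler_config(n_chains = 1, burn_in = 2000, retained = 15000, seed = 4,
    update_fields = FALSE, update_omega = FALSE, update_rho = FALSE,
    update_sigma = FALSE, store_fields = FALSE)
  fit <- svcmix(df, list(mix1 = "mix1_c1"), covariates = "cov1", config = cfg,
    init = list(beta0 = offset, beta = matrix(0, n, 1), omega = list(1),
      theta = 0, sigma_theta = 1))
  pkg_draws <- fit$chains$chain1$theta[, 1]

  set.seed(25)
  ref_draws <- reference_theta_mh(yobs, xcov, offset, sigma = 1)
  expect_equal(mean(pkg_draws), mean(ref_draws), tolerance = 0.05)
  expect_equal(sd(pkg_draws), sd(ref_draws), tolerance = 0.03)
})

test_that("adaptive blocks settle inside a sane acceptance window", {
  sim <- tiny_sim(n = 200, seed = 26)
  cfg <- sampler_config(n_chains = 1, burn_in = 800, retained = 800, seed = 5)
  fit <- suppressWarnings(svcmix(sim$data, sim$design$mixtures, config = cfg))
  rates <- fit$acceptance$rate
  expect_true(all(is.finite(rates)))
  expect_true(all(rates > 0.1 & rates < 0.6))
})

test_that("pooled summaries are invariant to chain relabeling", {
  sim <- tiny_sim(n = 30, seed = 27)
  cfg <- sampler_config(n_chains = 2, burn_in = 150, retained = 150, seed = 6)
  fit <- suppressWarnings(svcmix(sim$data, sim$design$mixtures, config = cfg))
  ws1 <- summarize_weights(fit)
  fit2 <- fit
  fit2$chains <- fit$chains[c(2, 1)]
  ws2 <- summarize_weights(fit2)
  expect_equal(ws1$mean, ws2$mean, tolerance = 1e-12)
  expect_equal(sort(pooled_draws(fit, "rho")), sort(pooled_draws(fit2, "rho")))
})

test_that("grid prediction at the observed sites returns the field draws", {
  sim <- tiny_sim(n = 20, seed = 28)
  cfg <- sampler_config(n_chains = 1, burn_in = 100, retained = 50, seed = 2,
    jitter = 1e-10)
  fit <- svcmix(sim$data, sim$design$mixtures, config = cfg)
  locs <- fit$data$locations
  D_oo <- as.matrix(dist(locs))
  ch <- fit$chains$chain1
  tau <- ch$sigma_beta[, 2]^-2
  gd <- svcmix:::.svm_grid_draws(ch$beta[[1]], ch$rho, tau,
    D_oo, D_oo, D_oo, 1e-10)
  expect_equal(gd, ch$beta[[1]], tolerance = 1e-3)
})

test_that("exceedance probabilities from grid draws are proportions", {
  sim <- tiny_sim(n = 25, seed = 29)
  cfg <- sampler_config(n_chains = 1, burn_in = 100, retained = 100, seed = 3)
  fit <- svcmix(sim$data, sim$design$mixtures, config = cfg)
  gp <- predict_grid(fit, grid_size = 5, bbox = c(0, 1, 0, 1), thin = 2)
  gs <- exceedance_summary(gp)
  expect_equal(nrow(gs), 25)
  expect_true(all(gs$p_above >= 0 & gs$p_above <= 1))
  expect_true(all(gs$p_below >= 0 & gs$p_below <= 1))
  expect_true(all(gs$p_above + gs$p_below <= 1 + 1e-12))
  expect_true(all(gs$flag %in% c(-1L, 0L, 1L)))
})
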