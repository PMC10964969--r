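#' MCMC sampler configuration
#'
#' Controls for posterior simulation. Defaults are desk-scale (2 chains of
#' 2000 burn-in + 2000 retained sweeps); production runs of 1e5+ iterations
#' are available by raising `burn_in`/`retained`.
#'
#' @param n_chains Number of independent chains (default 2).
#' @param burn_in Burn-in sweeps per chain; adaptation happens only here.
#' @param retained Retained (post-burn, post-thin) draws per chain.
#' @param thin Thinning interval for retained draws.
#' @param seed Integer seed; each chain uses a seed derived from it.
#' @param jitter Diagonal jitter for the spatial correlation matrix.
#' @param spatial_intercept Model the intercept as a spatial field (`TRUE`,
#'   the default) or as a single constant (`FALSE`).
#' @param likelihood Set `FALSE` for a prior-only run (the likelihood term is
#'   dropped; used to validate prior recovery).
#' @param update_fields,update_omega,update_theta,update_rho,update_sigma
#'   Enable/disable individual sweep blocks (all `TRUE` by default; mainly
#'   for validation runs that hold blocks fixed).
#' @param store_fields Store the full latent field draws (needed for grid
#'   prediction and coefficient summaries; default `TRUE`).
#' @param rho_every Attempt a spatial-range update every `rho_every` sweeps
#'   (default 1). Range updates dominate the per-sweep cost because they
#'   refactorize the correlation matrix.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 2, burn_in = 2000, retained = 2000,
                           thin = 1, seed = 1, jitter = 1e-6,
                           spatial_intercept = TRUE, likelihood = TRUE,
                           update_fields = TRUE, update_omega = TRUE,
                           update_theta = TRUE, update_rho = TRUE,
                           update_sigma = TRUE, store_fields = TRUE,
                           rho_every = 1) {
  stopifnot(n_chains >= 1, burn_in >= 0, retained >= 1, thin >= 1, rho_every >= 1)
  structure(
    list(
      n_chains = as.integer(n_chains), burn_in = as.integer(burn_in),
      retained = as.integer(retained), thin = as.integer(thin),
      seed = as.integer(seed), jitter = jitter,
      spatial_intercept = isTRUE(spatial_intercept),
      likelihood = isTRUE(likelihood),
      update_fields = isTRUE(update_fields), update_omega = isTRUE(update_omega),
      update_theta = isTRUE(update_theta), update_rho = isTRUE(update_rho),
      update_sigma = isTRUE(update_sigma), store_fields = isTRUE(store_fields),
      rho_every = as.integer(rho_every)
    ),
    class = "sampler_config"
  )
}

#' Fit the Bayesian spatially varying mixture model
#'
#' Runs multi-chain MCMC for the logistic group-index model with
#' Gaussian-process coefficient fields. Latent fields are updated by
#' elliptical slice sampling under their MVN prior; weight simplices by
#' adaptive random-walk Metropolis on the additive-log-ratio scale (target
#' acceptance 0.234); covariate effects, the spatial range and all scale
#' parameters by adaptive scalar random walks (target 0.44), the latter two
#' reflective on their uniform supports. Chains start from overdispersed
#' initial values and runs are reproducible given `config$seed`.
#'
#' @param data Data frame with one row per subject, or an [mixture_data()]
#'   object (then `mixtures`/`covariates`/... are ignored).
#' @param mixtures Named list of component column names, one entry per
#'   mixture.
#' @param covariates Optional character vector of covariate columns.
#' @param q Quantile bins for component scoring (default 4: quartiles).
#' @param config A [sampler_config()].
#' @param priors A [prior_spec()]; `rho_bounds` defaults to the observed
#'   inter-point distance range.
#' @param coords,outcome,id Column names passed to [mixture_data()].
#' @param init Optional named list overriding initial values (`beta0`,
#'   `beta`, `omega`, `theta`, `rho`, `sigma_beta`, `sigma_theta`); each
#'   override is applied to every chain.
#' @return An object of class `svcmix_fit` with elements `chains` (per-chain
#'   retained draws), `psrf` (Gelman-Rubin table for all scalar parameters),
#'   `acceptance`, the quantized scores, and the inputs needed downstream.
#' @export
svcmix <- function(data, mixtures, covariates = NULL, q = 4,
                   config = sampler_config(), priors = prior_spec(),
                   coords = c("x", "y"), outcome = "outcome", id = NULL,
                   init = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(data, "svcmix_data")) {
    data <- mixture_data(data, mixtures, covariates = covariates,
      coords = coords, outcome = outcome, id = id, q = q)
  }
  quantized <- quantize_components(data)
  rb <- priors$rho_bounds
  if (is.null(rb)) rb <- pairwise_distance_bounds(data$locations)
  alpha <- resolve_alpha(priors, data$design)
  C <- length(quantized)
  B <- ncol(data$covariates)
  n <- data$n
  D <- as.matrix(dist(data$locations))

  ctrl <- config[c("burn_in", "retained", "thin", "jitter", "spatial_intercept",
    "likelihood", "update_fields", "update_omega", "update_theta",
    "update_rho", "update_sigma", "store_fields", "rho_every")]
  prior_list <- list(alpha = alpha, sigma_upper = priors$sigma_upper,
    rho_min = rb[[1]], rho_max = rb[[2]])

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 77777L * (ch - 1L))
    ini <- overdispersed_init(n, C, B, D, rb, alpha, config)
    if (!is.null(init)) ini[names(init)] <- init
    chains[[ch]] <- .svm_run_chain(
      y = data$outcome,
      qmats = lapply(quantized, function(m) matrix(as.numeric(m), nrow(m))),
      X = data$covariates, D = D, init = ini, prior = prior_list, ctrl = ctrl
    )
  }
  # arma vectors come back as K x 1 matrices; flatten the scalar chains
  chains <- lapply(chains, function(ch) {
    ch$rho <- as.numeric(ch$rho)
    ch$loglik <- as.numeric(ch$loglik)
    ch
  })
  names(chains) <- paste0("chain", seq_along(chains))

  fit <- structure(
    list(
      data = data, quantized = quantized, priors = priors, config = config,
      rho_bounds = rb, chains = chains,
      runtime = proc.time()[["elapsed"]] - t0
    ),
    class = "svcmix_fit"
  )
  fit$psrf <- psrf_table(fit)
  fit$acceptance <- acceptance_table(fit)
  not_conv <- dplyr::filter(fit$psrf, is.finite(.data$psrf), .data$psrf >= 1.1)
  if (nrow(not_conv) > 0L && config$n_chains >= 2L) {
    warn(paste0(
      "Gelman-Rubin statistic >= 1.1 for: ",
      paste(utils::head(not_conv$parameter, 10), collapse = ", "),
      if (nrow(not_conv) > 10) ", ..." else ""
    ), class = "svcmix_convergence_warning")
  }
  fit
}

#' @export
print.svcmix_fit <- function(x, ...) {
  cfg <- x$config
  cat("<svcmix_fit> ", x$data$n, " subjects, ", length(x$quantized), " mixture(s); ",
    cfg$n_chains, " chain(s) x (", cfg$burn_in, " burn-in + ",
    cfg$retained, " retained, thin ", cfg$thin, ")\n", sep = "")
  max_psrf <- if (all(is.na(x$psrf$psrf))) NA_real_ else max(x$psrf$psrf, na.rm = TRUE)
  cat("  max Gelman-Rubin: ", round(max_psrf, 3),
    "  (", sum(x$psrf$psrf < 1.1, na.rm = TRUE), "/", nrow(x$psrf),
    " scalar parameters < 1.1)\n", sep = "")
  cat("  elapsed: ", round(x$runtime, 1), "s\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic PSRF for one scalar parameter observed in two or more chains:
#' with within-chain variance `W` and between-chain variance `B` (of chain
#' means, times the chain length `n`), the statistic is
#' `sqrt((n - 1)/n + B/(n W))`.
#'
#' @param draws Matrix with one column per chain (iterations x chains), or a
#'   list of equal-length numeric vectors.
#' @return The PSRF; `NA` (undefined diagnostic) when the within-chain
#'   variance is zero.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  m <- ncol(draws)
  n <- nrow(draws)
  if (m < 2L) abort("At least two chains are required.")
  if (n < 10L) abort("At least 10 draws per chain are required.")
  W <- mean(apply(draws, 2, var))
  Bn <- n * var(colMeans(draws))
  if (W == 0) return(NA_real_)
  sqrt((n - 1) / n + Bn / (n * W))
}

#' Pooled draws of a scalar parameter
#'
#' @param fit An `svcmix_fit`.
#' @param what One of `"rho"`, `"omega"`, `"theta"`, `"sigma_beta"`,
#'   `"sigma_theta"`, `"loglik"`.
#' @param mixture,index Mixture number and component/column index where
#'   applicable.
#' @return Numeric vector pooling retained draws across chains.
#' @export
pooled_draws <- function(fit, what = "rho", mixture = 1, index = 1) {
  per_chain <- lapply(fit$chains, function(ch) {
    switch(what,
      rho = ch$rho,
      loglik = ch$loglik,
      omega = ch$omega[[mixture]][, index],
      theta = ch$theta[, index],
      sigma_beta = ch$sigma_beta[, index],
      sigma_theta = ch$sigma_theta[, index],
      abort("Unknown draw type.")
    )
  })
  unlist(per_chain, use.names = FALSE)
}

#' Posterior means of the coefficient fields at the subject locations
#'
#' @param fit An `svcmix_fit` run with `store_fields = TRUE`.
#' @return Tibble with `id`, `x`, `y`, one `beta0` column and one column per
#'   mixture field, pooling chains.
#' @export
field_posterior_means <- function(fit) {
  stopifnot(fit$config$store_fields)
  nm <- names(fit$quantized)
  out <- tibble(
    id = fit$data$ids,
    x = fit$data$locations[, 1], y = fit$data$locations[, 2],
    beta0 = colMeans(do.call(rbind, lapply(fit$chains, `[[`, "beta0")))
  )
  for (j in seq_along(nm)) {
    out[[paste0("beta_", nm[j])]] <-
      colMeans(do.call(rbind, lapply(fit$chains, function(ch) ch$beta[[j]])))
  }
  out
}

#' Kriged posterior draws of coefficient surfaces on a regular grid
#'
#' For (a thinned subset of) retained iterations, draws each requested field
#' jointly at the grid cell centers from the conditional multivariate normal
#' given that iteration's field values, spatial range and field precision
#' (full uncertainty propagation rather than a posterior-mean plug-in).
#'
#' @param fit An `svcmix_fit` with stored fields.
#' @param grid_size Cells per side (default 30).
#' @param bbox Grid bounding box `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   bounding box of the subject locations.
#' @param thin Use every `thin`-th retained iteration per chain; the default
#'   targets about 150 iterations per chain.
#' @param fields Character vector of fields to predict: mixture names and/or
#'   `"beta0"`; default all mixture fields.
#' @param seed Optional seed for the kriging draws (set locally); leave
#'   `NULL` to consume the current RNG stream.
#' @return An object of class `svcmix_grid`: the grid tibble plus one
#'   `K x n_cells` draw matrix per field (chains pooled).
#' @export
predict_grid <- function(fit, grid_size = 30, bbox = NULL, thin = NULL,
                         fields = NULL, seed = NULL) {
  stopifnot(fit$config$store_fields)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(bbox)) {
    bbox <- c(range(fit$data$locations[, 1]), range(fit$data$locations[, 2]))
  }
  if (is.null(thin)) thin <- max(1L, fit$config$retained %/% 150L)
  if (is.null(fields)) fields <- names(fit$quantized)
  grid <- grid_centers(grid_size, bbox)
  glocs <- as.matrix(grid)
  D_oo <- as.matrix(dist(fit$data$locations))
  D_no <- cross_distance(glocs, fit$data$locations)
  D_nn <- as.matrix(dist(glocs))
  keep <- seq(1L, fit$config$retained, by = thin)

  draws <- lapply(fields, function(f) {
    j <- if (f == "beta0") 0L else match(f, names(fit$quantized))
    if (is.na(j)) abort(paste0("Unknown field '", f, "'."))
    per_chain <- lapply(fit$chains, function(ch) {
      fd <- if (j == 0L) ch$beta0[keep, , drop = FALSE] else ch$beta[[j]][keep, , drop = FALSE]
      tau <- ch$sigma_beta[keep, j + 1L]^-2
      .svm_grid_draws(fd, ch$rho[keep], tau, D_oo, D_no, D_nn, fit$config$jitter)
    })
    do.call(rbind, per_chain)
  })
  names(draws) <- fields
  structure(
    list(grid = grid, draws = draws, grid_size = grid_size, bbox = bbox,
      thin = thin, n_draws = length(keep) * fit$config$n_chains),
    class = "svcmix_grid"
  )
}

#' @export
print.svcmix_grid <- function(x, ...) {
  cat("<svcmix_grid> ", x$grid_size, "x", x$grid_size, " cells, ",
    x$n_draws, " posterior draws per field: ",
    paste(names(x$draws), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# --- internal ---------------------------------------------------------------

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

overdispersed_init <- function(n, C, B, D, rb, alpha, config) {
  rho0 <- runif(1, rb[[1]], rb[[2]])
  Omega <- matern32_correlation(D, rho0)
  dim(Omega) <- dim(D)
  diag(Omega) <- 1 + config$jitter
  L <- t(chol(Omega))
  field_draw <- function() drop(L %*% rnorm(n)) # prior draw at sigma_beta = 1
  list(
    beta0 = if (config$spatial_intercept) field_draw() else rep(rnorm(1), n),
    beta = matrix(replicate(C, field_draw()), nrow = n),
    omega = lapply(alpha, rdirichlet1),
    theta = rnorm(B),
    rho = rho0,
    sigma_beta = rep(1, C + 1),
    sigma_theta = rep(1, B)
  )
}

psrf_table <- function(fit) {
  nm <- names(fit$quantized)
  entries <- list()
  add <- function(name, per_chain) {
    entries[[length(entries) + 1L]] <<- tibble(
      parameter = name,
      psrf = if (fit$config$n_chains >= 2L) gelman_rubin(per_chain) else NA_real_
    )
  }
  for (j in seq_along(nm)) {
    for (k in seq_len(ncol(fit$chains[[1]]$omega[[j]]))) {
      add(paste0("omega_", nm[j], "_", k),
        lapply(fit$chains, function(ch) ch$omega[[j]][, k]))
    }
  }
  B <- ncol(fit$chains[[1]]$theta)
  for (b in seq_len(B)) {
    add(paste0("theta_", b), lapply(fit$chains, function(ch) ch$theta[, b]))
    add(paste0("sigma_theta_", b), lapply(fit$chains, function(ch) ch$sigma_theta[, b]))
  }
  add("rho", lapply(fit$chains, function(ch) ch$rho))
  for (f in seq_len(ncol(fit$chains[[1]]$sigma_beta))) {
    add(paste0("sigma_beta_", f), lapply(fit$chains, function(ch) ch$sigma_beta[, f]))
  }
  out <- dplyr::bind_rows(entries)
  out$converged <- !is.na(out$psrf) & out$psrf < 1.1
  out
}

acceptance_table <- function(fit) {
  purrr::imap_dfr(fit$chains, function(ch, chain) {
    a <- ch$acceptance
    tibble(
      chain = chain,
      block = c(
        paste0("omega_", names(fit$quantized)),
        if (length(a$theta)) paste0("theta_", seq_along(a$theta)),
        "rho",
        paste0("sigma_beta_", seq_along(a$sigma_beta)),
        if (length(a$sigma_theta)) paste0("sigma_theta_", seq_along(a$sigma_theta))
      ),
      rate = c(a$omega, a$theta, a$rho, a$sigma_beta, a$sigma_theta)
    )
  })
}
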