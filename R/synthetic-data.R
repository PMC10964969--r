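#' True-effect surface specification
#'
#' Describes the mean surface of a spatially varying coefficient on the unit
#' square, from which per-location true effects are drawn with a small
#' normal perturbation.
#'
#' Patterns:
#' * `"constant"` — one global mean everywhere;
#' * `"one_dim"` — three vertical bands split at x = 1/3 and x = 2/3 with
#'   separate means (left, middle, right);
#' * `"radial"` — mean decaying linearly with distance from the center
#'   (0.5, 0.5), from `center_mean` at r = 0 to `boundary_value` at r = 0.5,
#'   clamped beyond.
#'
#' @param pattern One of `"constant"`, `"one_dim"`, `"radial"`.
#' @param constant_mean Mean for the constant pattern.
#' @param band_means Length-3 means (left, middle, right) for `one_dim`.
#' @param center_mean,boundary_value Radial profile endpoints.
#' @param sd Perturbation standard deviation (default 0.1).
#' @return An object of class `surface_spec`.
#' @export
surface_spec <- function(pattern = c("constant", "one_dim", "radial"),
                         constant_mean = 0, band_means = c(3, 1.5, 0),
                         center_mean = 3, boundary_value = 0, sd = 0.1) {
  pattern <- match.arg(pattern)
  stopifnot(sd >= 0, length(band_means) == 3)
  structure(list(pattern = pattern, constant_mean = constant_mean,
    band_means = band_means, center_mean = center_mean,
    boundary_value = boundary_value, sd = sd), class = "surface_spec")
}

#' True mean of an effect surface at given locations
#'
#' @param spec A [surface_spec()].
#' @param locations n x 2 coordinates in the unit square.
#' @return Numeric vector of surface means.
#' @export
true_mean_surface <- function(spec, locations) {
  locations <- as_location_matrix(locations)
  x <- locations[, 1]
  switch(spec$pattern,
    constant = rep(spec$constant_mean, nrow(locations)),
    one_dim = {
      band <- 1L + (x >= 1 / 3) + (x >= 2 / 3)
      spec$band_means[band]
    },
    radial = {
      r <- sqrt((x - 0.5)^2 + (locations[, 2] - 0.5)^2)
      frac <- pmin(r / 0.5, 1)
      spec$center_mean + (spec$boundary_value - spec$center_mean) * frac
    }
  )
}

#' Uniform subject locations on the unit square
#'
#' @param n Number of subjects.
#' @param seed Optional seed (set locally).
#' @return n x 2 matrix of coordinates in (0, 1)^2.
#' @export
sample_locations <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(x = runif(n), y = runif(n))
}

#' Correlated raw component concentrations
#'
#' Draws n rows from a zero-mean, unit-variance multivariate normal with the
#' given correlation matrix. (Component means are irrelevant downstream
#' because quantile scoring is location-invariant.)
#'
#' @param n Number of subjects.
#' @param corr Symmetric positive-definite correlation matrix.
#' @param seed Optional seed.
#' @return n x ncol(corr) matrix.
#' @export
sample_components <- function(n, corr, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  corr <- as.matrix(corr)
  if (!isSymmetric(corr, tol = 1e-10)) abort("Correlation matrix must be symmetric.")
  R <- tryCatch(chol(corr), error = function(e) {
    abort("Correlation matrix is not positive definite.", parent = e)
  })
  z <- matrix(rnorm(n * ncol(corr)), n)
  m <- z %*% R
  colnames(m) <- colnames(corr)
  m
}

#' Per-location true coefficient values
#'
#' Draws `N(true_mean_surface(s), sd)` at each location.
#'
#' @inheritParams true_mean_surface
#' @param seed Optional seed.
#' @return Numeric vector of true effects.
#' @export
sample_effects <- function(spec, locations, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- true_mean_surface(spec, locations)
  rnorm(length(mu), mu, spec$sd)
}

#' Calibrate the global intercept for a 1:1 case-control ratio
#'
#' Finds `b0` such that the average case probability
#' `mean(plogis(b0 + rowSums(effects * indices)))` equals one half, by
#' bisection on `[-20, 20]` to tolerance 1e-8.
#'
#' @param effects n x C matrix (or n-vector) of true coefficient values.
#' @param weights List of C simplex weight vectors.
#' @param quantized List of C quantile-score matrices.
#' @return Scalar intercept.
#' @export
calibrate_intercept <- function(effects, weights, quantized) {
  lp <- mixture_contribution(effects, weights, quantized)
  f <- function(b0) mean(stats::plogis(b0 + lp)) - 0.5
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    abort("No sign change on [-20, 20]; cannot calibrate the intercept.")
  }
  while (hi - lo > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Bernoulli outcomes from calibrated true effects
#'
#' @inheritParams calibrate_intercept
#' @param b0 Calibrated intercept.
#' @param seed Optional seed.
#' @return Integer 0/1 outcome vector with case fraction centered at 1/2.
#' @export
simulate_outcomes <- function(effects, weights, quantized, b0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- stats::plogis(b0 + mixture_contribution(effects, weights, quantized))
  as.integer(runif(length(p)) < p)
}

#' Simulation scenario specification
#'
#' Built-in presets follow the simulation design: locations uniform on the
#' unit square, six components per mixture drawn from multivariate normals
#' with fixed correlation structure, true weights
#' `omega1 = (0.30, 0.20, 0.20, 0.13, 0.10, 0.07)` and
#' `omega2 = (0.45, 0.15, 0.15, 0.15, 0.05, 0.05)`, quartile scoring, effect
#' surfaces perturbed with SD 0.1, and outcomes calibrated to an
#' approximately 1:1 case:control ratio.
#'
#' Presets (keyed by spatial pattern):
#' * `"constant_null"` — one mixture, constant mean 0;
#' * `"one_dim"` — one mixture, band means 3 / 1.5 / 0;
#' * `"radial"` — one mixture, radial 3 -> 0;
#' * `"two_mix_one_dim"` — spatially varying (one_dim) mixture plus a second
#'   constant mixture with mean 1;
#' * `"two_mix_radial"` — radial mixture plus the constant-mean-1 mixture.
#'
#' @param scenario Preset name.
#' @param n Subjects per dataset (default 1000).
#' @param D Number of datasets (default 50).
#' @param seed Base seed; dataset d uses a seed derived from it.
#' @param q Quantile bins (default 4).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("constant_null", "one_dim", "radial",
                                       "two_mix_one_dim", "two_mix_radial"),
                          n = 1000, D = 50, seed = 1, q = 4) {
  scenario <- match.arg(scenario)
  mix1 <- list(
    omega = c(0.30, 0.20, 0.20, 0.13, 0.10, 0.07),
    corr = preset_correlation(1)
  )
  mix2 <- list(
    omega = c(0.45, 0.15, 0.15, 0.15, 0.05, 0.05),
    corr = preset_correlation(2),
    surface = surface_spec("constant", constant_mean = 1)
  )
  mixtures <- switch(scenario,
    constant_null = list(mix1 = c(mix1, list(surface = surface_spec("constant", constant_mean = 0)))),
    one_dim = list(mix1 = c(mix1, list(surface = surface_spec("one_dim")))),
    radial = list(mix1 = c(mix1, list(surface = surface_spec("radial")))),
    two_mix_one_dim = list(
      mix1 = c(mix1, list(surface = surface_spec("one_dim"))), mix2 = mix2),
    two_mix_radial = list(
      mix1 = c(mix1, list(surface = surface_spec("radial"))), mix2 = mix2)
  )
  structure(list(scenario = scenario, mixtures = mixtures, n = as.integer(n),
    D = as.integer(D), seed = as.integer(seed), q = as.integer(q)),
  class = "scenario_spec")
}

#' Component correlation matrices used by the simulation presets
#'
#' @param which 1 (first mixture) or 2 (second mixture).
#' @return A 6 x 6 correlation matrix.
#' @export
preset_correlation <- function(which = 1) {
  if (which == 1) {
    m <- rbind(
      c(1.0, 0.3, 0.2, 0.1, 0, 0),
      c(0.3, 1.0, 0.2, 0.1, 0, 0),
      c(0.2, 0.2, 1.0, 0.1, 0, 0),
      c(0.1, 0.1, 0.1, 1.0, 0, 0),
      c(0.0, 0.0, 0.0, 0.0, 1, 0),
      c(0.0, 0.0, 0.0, 0.0, 0, 1)
    )
  } else {
    m <- rbind(
      c(1.0, 0.2, 0.1, 0.1, 0, 0),
      c(0.2, 1.0, 0.2, 0.1, 0, 0),
      c(0.1, 0.2, 1.0, 0.1, 0, 0),
      c(0.1, 0.1, 0.1, 1.0, 0, 0),
      c(0.0, 0.0, 0.0, 0.0, 1, 0),
      c(0.0, 0.0, 0.0, 0.0, 0, 1)
    )
  }
  m
}

#' Generate a full simulation scenario
#'
#' Produces `D` independent case-control datasets with retained ground truth
#' (true per-location effects, true mean surfaces, true weights, calibrated
#' intercept). Each dataset has its own derived seed, so generation is
#' reproducible bit-for-bit from `(scenario, seed)`.
#'
#' @param spec A [scenario_spec()] (or a preset name, then `...` is passed to
#'   [scenario_spec()]).
#' @param ... Passed to [scenario_spec()] when `spec` is a name.
#' @return List of `D` simulated datasets; each element has `data` (tibble:
#'   `id, x, y, outcome`, component columns `<mix>_c<k>`), `truth` (tibble:
#'   `id, x, y, true_beta_<mix>, true_mean_<mix>`), `weights`, `b0`,
#'   `scenario`, `seed` and the `mixture_design`.
#' @export
simulate_scenario <- function(spec, ...) {
  if (is.character(spec)) spec <- scenario_spec(spec, ...)
  lapply(seq_len(spec$D), function(d) {
    simulate_one_dataset(spec, seed = spec$seed + 7919L * d)
  })
}

simulate_one_dataset <- function(spec, seed) {
  set.seed(seed)
  n <- spec$n
  locs <- sample_locations(n)
  comps <- lapply(spec$mixtures, function(mx) sample_components(n, mx$corr))
  effects <- vapply(spec$mixtures, function(mx) sample_effects(mx$surface, locs),
    numeric(n))
  weights <- lapply(spec$mixtures, `[[`, "omega")
  quantized <- lapply(comps, quantize_components, q = spec$q)
  b0 <- calibrate_intercept(effects, weights, quantized)
  y_outcome <- simulate_outcomes(effects, weights, quantized, b0)

  nm <- names(spec$mixtures)
  data <- tibble(id = seq_len(n), x = locs[, 1], y = locs[, 2],
    outcome = y_outcome)
  for (j in seq_along(nm)) {
    cm <- comps[[j]]
    colnames(cm) <- paste0(nm[j], "_c", seq_len(ncol(cm)))
    data <- dplyr::bind_cols(data, as_tibble(cm))
  }
  truth <- tibble(id = seq_len(n), x = locs[, 1], y = locs[, 2])
  for (j in seq_along(nm)) {
    truth[[paste0("true_beta_", nm[j])]] <- effects[, j]
    truth[[paste0("true_mean_", nm[j])]] <-
      true_mean_surface(spec$mixtures[[j]]$surface, locs)
  }
  design <- mixture_design(
    lapply(setNames(nm, nm), function(m) {
      paste0(m, "_c", seq_len(ncol(comps[[m]])))
    }),
    q = spec$q
  )
  list(data = data, truth = truth, weights = weights, b0 = b0,
    scenario = spec$scenario, seed = seed, design = design)
}

# sum_j effects[, j] * group_index_j
mixture_contribution <- function(effects, weights, quantized) {
  effects <- as.matrix(effects)
  lp <- 0
  for (j in seq_along(weights)) {
    lp <- lp + effects[, j] * group_index(quantized[[j]], weights[[j]])
  }
  lp
}
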