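#' Run a scaled simulation-study replicate in memory
#'
#' For one scenario: simulate `D` datasets, fit the model to each, krige the
#' coefficient surfaces onto a regular grid, summarize exceedance, score
#' against the truth, and aggregate. This is the engine behind
#' [cli_replicate()] and the package's validation runs.
#'
#' @param scenario Scenario preset name (see [scenario_spec()]).
#' @param D Number of datasets.
#' @param n Subjects per dataset.
#' @param seed Base seed for generation; fits use derived seeds.
#' @param config A [sampler_config()] (its `seed` is re-derived per dataset).
#' @param grid_size Prediction grid side length (default 30).
#' @param threshold Exceedance significance threshold (default 0.95).
#' @param bbox Grid bounding box; the simulation study region is the unit
#'   square.
#' @param grid_thin Thinning interval for grid-prediction draws (default as
#'   in [predict_grid()]).
#' @param keep_fits Keep the fitted objects (memory-heavy; default `FALSE`).
#' @return List: `aggregate` (scenario-level metric tibble), `per_dataset`
#'   (list of per-dataset report tibbles), `mean_grid` (tibble of
#'   across-dataset mean predicted coefficient surfaces), `weights`
#'   (per-dataset weight summaries), optionally `fits`.
#' @export
run_simulation_study <- function(scenario, D = 3, n = 500, seed = 1,
                                 config = sampler_config(),
                                 grid_size = 30, threshold = 0.95,
                                 bbox = c(0, 1, 0, 1), grid_thin = NULL,
                                 keep_fits = FALSE) {
  sims <- simulate_scenario(scenario, n = n, D = D, seed = seed)
  reports <- vector("list", D)
  weights <- vector("list", D)
  grids <- vector("list", D)
  fits <- if (keep_fits) vector("list", D) else NULL
  for (d in seq_len(D)) {
    sim <- sims[[d]]
    cfg <- config
    cfg$seed <- config$seed + 7919L * d
    fit <- svcmix(sim$data, sim$design$mixtures, q = sim$design$q, config = cfg)
    gp <- predict_grid(fit, grid_size = grid_size, bbox = bbox, thin = grid_thin)
    gs <- exceedance_summary(gp, threshold = threshold)
    reports[[d]] <- evaluate_fit(fit, sim, gs)
    weights[[d]] <- summarize_weights(fit)
    grids[[d]] <- dplyr::select(as_tibble(gs), "field", "x", "y", "mean")
    if (keep_fits) fits[[d]] <- fit
  }
  mean_grid <- dplyr::bind_rows(grids, .id = "dataset") |>
    dplyr::group_by(.data$field, .data$x, .data$y) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
  out <- list(
    scenario = scenario, D = D, n = n, seed = seed,
    aggregate = aggregate_reports(reports),
    per_dataset = reports, weights = weights, mean_grid = mean_grid
  )
  if (keep_fits) out$fits <- fits
  out
}

#' Pipeline stage: simulate datasets to disk
#'
#' Writes `dataset_<d>.csv` and `truth_<d>.csv` for each of `D` datasets of
#' the named scenario, plus a `manifest.json` recording the scenario, sizes,
#' every derived seed, the true weights and the calibrated intercepts.
#'
#' @inheritParams run_simulation_study
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
cli_simulate <- function(scenario, D = 2, n = 200, seed = 1, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sims <- simulate_scenario(scenario, n = n, D = D, seed = seed)
  for (d in seq_len(D)) {
    write_mixture_data(sims[[d]]$data, file.path(dir, sprintf("dataset_%d.csv", d)))
    readr::write_csv(sims[[d]]$truth, file.path(dir, sprintf("truth_%d.csv", d)))
  }
  manifest <- list(
    scenario = scenario, D = D, n = n, base_seed = seed,
    dataset_seeds = vapply(sims, `[[`, integer(1), "seed"),
    true_weights = sims[[1]]$weights,
    calibrated_intercepts = vapply(sims, `[[`, numeric(1), "b0")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Pipeline stage: fit one dataset from disk
#'
#' Reads a dataset CSV (components detected by the `<mixture>_c<k>` naming
#' convention), runs the MCMC, and writes the scalar draws (long CSV), the
#' Gelman-Rubin table with convergence flags, per-block acceptance rates, a
#' diagnostics JSON (seed, iteration counts, runtime), and the binary fit
#' container used by the later stages.
#'
#' @param dataset_path Dataset CSV.
#' @param dir Output directory.
#' @param config A [sampler_config()].
#' @param covariates Optional covariate column names.
#' @param q Quantile bins.
#' @return The fit, invisibly. A PSRF >= 1.1 raises a
#'   `svcmix_convergence_warning`, not an error.
#' @export
cli_fit <- function(dataset_path, dir = ".", config = sampler_config(),
                    covariates = NULL, q = 4) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data <- read_mixture_data(dataset_path)
  mixtures <- detect_mixtures(data)
  fit <- svcmix(data, mixtures, covariates = covariates, q = q,
    config = config, id = if ("id" %in% names(data)) "id" else NULL)
  write_draws(fit, file.path(dir, "draws.csv"))
  readr::write_csv(fit$psrf, file.path(dir, "psrf.csv"))
  readr::write_csv(fit$acceptance, file.path(dir, "acceptance.csv"))
  jsonlite::write_json(
    list(
      dataset = dataset_path, n = fit$data$n,
      mixtures = purrr::map_int(fit$quantized, ncol),
      seed = config$seed, n_chains = config$n_chains,
      burn_in = config$burn_in, retained = config$retained, thin = config$thin,
      max_psrf = if (all(is.na(fit$psrf$psrf))) NA_real_ else max(fit$psrf$psrf, na.rm = TRUE),
      all_converged = all(fit$psrf$converged | is.na(fit$psrf$psrf)),
      runtime_s = fit$runtime
    ),
    file.path(dir, "diagnostics.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  save_fit(fit, file.path(dir, "fit.rds"))
  invisible(fit)
}

#' Pipeline stage: grid prediction and exceedance export
#'
#' @param fit An `svcmix_fit` or a path to a saved fit container.
#' @param path Output CSV for the gridded summary.
#' @param grid_size,threshold,bbox As in [predict_grid()] /
#'   [exceedance_summary()].
#' @param grid_thin Thinning interval for grid-prediction draws.
#' @param seed Seed for the kriging draws (default 1 so repeated calls on the
#'   same fit reproduce the same summary).
#' @return The grid summary, invisibly.
#' @export
cli_predict <- function(fit, path, grid_size = 30, threshold = 0.95, bbox = NULL,
                        grid_thin = NULL, seed = 1) {
  if (is.character(fit)) fit <- read_fit(fit)
  gp <- predict_grid(fit, grid_size = grid_size, bbox = bbox, thin = grid_thin,
    seed = seed)
  gs <- exceedance_summary(gp, threshold = threshold)
  export_maps(gs, path)
  invisible(gs)
}

#' Pipeline stage: score a fit against its simulation truth
#'
#' @param fit An `svcmix_fit` or saved-fit path.
#' @param truth_path Truth CSV written by [cli_simulate()].
#' @param scenario Scenario preset name (supplies the true weights and the
#'   stratum definitions).
#' @param dir Output directory for `metrics.json` / `metrics.csv`.
#' @param grid_summary Optional [exceedance_summary()] (or its CSV path) for
#'   stratum proportions.
#' @return The per-dataset report tibble, invisibly.
#' @export
cli_evaluate <- function(fit, truth_path, scenario, dir = ".",
                         grid_summary = NULL) {
  if (is.character(fit)) fit <- read_fit(fit)
  if (is.character(grid_summary)) grid_summary <- read_maps(grid_summary)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- readr::read_csv(truth_path, show_col_types = FALSE)
  spec <- scenario_spec(scenario)
  sim <- list(truth = truth, weights = lapply(spec$mixtures, `[[`, "omega"),
    scenario = scenario)
  report <- evaluate_fit(fit, sim, grid_summary)
  write_metrics_report(aggregate_reports(report),
    json_path = file.path(dir, "metrics.json"),
    csv_path = file.path(dir, "metrics.csv"))
  invisible(report)
}

#' Pipeline stage: full scaled-down simulation-study replicate
#'
#' Simulate, fit, predict and evaluate `D` datasets of one scenario, writing
#' the scenario-level metric table (JSON + flat CSV), the across-dataset mean
#' predicted coefficient grid, and a resolved-run manifest.
#'
#' @inheritParams run_simulation_study
#' @param dir Output directory.
#' @return The `run_simulation_study()` result, invisibly.
#' @export
cli_replicate <- function(scenario, D = 2, n = 200, seed = 1,
                          config = sampler_config(), grid_size = 30,
                          threshold = 0.95, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- run_simulation_study(scenario, D = D, n = n, seed = seed,
    config = config, grid_size = grid_size, threshold = threshold)
  write_metrics_report(res$aggregate,
    json_path = file.path(dir, "metrics.json"),
    csv_path = file.path(dir, "metrics.csv"))
  readr::write_csv(res$mean_grid, file.path(dir, "mean_grid.csv"))
  jsonlite::write_json(
    list(scenario = scenario, D = D, n = n, seed = seed,
      n_chains = config$n_chains, burn_in = config$burn_in,
      retained = config$retained, grid_size = grid_size, threshold = threshold),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(res)
}
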