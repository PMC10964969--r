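#' Coefficient mean square error
#'
#' MSE between the true mean surface values at the subject locations and the
#' per-subject posterior-mean coefficients.
#'
#' @param true_means,posterior_means Equal-length numeric vectors.
#' @return Scalar MSE.
#' @export
coefficient_mse <- function(true_means, posterior_means) {
  if (length(true_means) != length(posterior_means)) abort("Length mismatch.")
  mean((true_means - posterior_means)^2)
}

#' Importance-weight recovery errors
#'
#' MSE and absolute error between a true weight simplex and the posterior
#' means of the estimated one. The absolute error is reported both as the
#' mean and as the median of the componentwise absolute errors (the two
#' conventions in circulation); the study-level tables use the mean form.
#'
#' @param true_omega,estimated_omega Equal-length simplex vectors.
#' @return Named list: `mse`, `mae_mean`, `mae_median`.
#' @export
weights_error <- function(true_omega, estimated_omega) {
  if (length(true_omega) != length(estimated_omega)) abort("Length mismatch.")
  ae <- abs(true_omega - estimated_omega)
  list(mse = mean(ae^2), mae_mean = mean(ae), mae_median = median(ae))
}

#' Pearson correlation between two estimated coefficient fields
#'
#' @param field1,field2 Posterior-mean coefficient vectors across subjects.
#' @return Pearson r.
#' @export
coefficient_correlation <- function(field1, field2) {
  if (sd(field1) == 0 || sd(field2) == 0) {
    abort("Zero variance in a coefficient field; correlation undefined.")
  }
  cor(field1, field2)
}

#' Strata of the study region for significance-proportion summaries
#'
#' Returns the region partition appropriate to a spatial pattern, as named
#' predicate functions of cell coordinates:
#' * `one_dim` — vertical thirds split at x = 1/3 and 2/3;
#' * `radial` — nested central disks where the true mean is at least 2, 1,
#'   and 0.25 (linear decay from 3 at the center to 0 at r = 0.5);
#' * `constant` — the whole region.
#'
#' @param pattern `"constant"`, `"one_dim"` or `"radial"`.
#' @param spec Optional [surface_spec()] for the radial mean profile.
#' @return Named list of `function(x, y)` predicates, with attribute
#'   `two_sided` (`TRUE` only for a null constant surface).
#' @export
scenario_strata <- function(pattern, spec = NULL) {
  if (is.null(spec)) {
    spec <- switch(pattern,
      constant = surface_spec("constant", constant_mean = 0),
      one_dim = surface_spec("one_dim"),
      radial = surface_spec("radial")
    )
  }
  strata <- switch(pattern,
    constant = list(
      all = function(x, y) rep(TRUE, length(x))
    ),
    one_dim = list(
      left = function(x, y) x < 1 / 3,
      middle = function(x, y) x >= 1 / 3 & x < 2 / 3,
      right = function(x, y) x >= 2 / 3
    ),
    radial = {
      mk <- function(level) {
        force(level)
        function(x, y) true_mean_surface(spec, cbind(x, y)) >= level
      }
      list(mean_ge_2 = mk(2), mean_ge_1 = mk(1), mean_ge_0.25 = mk(0.25))
    },
    abort("Unknown pattern.")
  )
  # a truly null constant surface counts significance in either direction
  attr(strata, "two_sided") <-
    pattern == "constant" && isTRUE(all(spec$constant_mean == 0))
  strata
}

#' Proportion of significant grid cells per stratum
#'
#' For each stratum, the fraction of its grid cells flagged significantly
#' elevated (`flag == +1`), or significant in either direction when the
#' strata describe a null constant surface (two-sided counting).
#'
#' @param cells Tibble with columns `x`, `y`, `flag` for one field (e.g. one
#'   field of an [exceedance_summary()]).
#' @param strata A [scenario_strata()] list (or a pattern name).
#' @return Tibble with `stratum`, `n_cells`, `proportion`.
#' @export
significant_proportion_by_stratum <- function(cells, strata) {
  if (is.character(strata)) strata <- scenario_strata(strata)
  two_sided <- isTRUE(attr(strata, "two_sided"))
  purrr::imap_dfr(strata, function(pred, nm) {
    inside <- pred(cells$x, cells$y)
    if (!any(inside)) abort(paste0("Stratum '", nm, "' contains no cells."))
    fl <- cells$flag[inside]
    tibble(
      stratum = nm, n_cells = sum(inside),
      proportion = if (two_sided) mean(fl != 0) else mean(fl == 1L)
    )
  })
}

#' Score one fitted model against its simulation truth
#'
#' Computes the per-dataset performance metrics: coefficient MSE per mixture
#' (true mean surface vs posterior-mean field at the subject locations),
#' weight-recovery MSE/MAE per mixture, the proportion of significant grid
#' cells per stratum of the spatial pattern, and (for two-mixture fits) the
#' Pearson correlation between the two posterior-mean coefficient fields.
#'
#' @param fit An `svcmix_fit` for one simulated dataset.
#' @param sim The matching element of [simulate_scenario()] output (carries
#'   `truth`, `weights` and the scenario label).
#' @param grid_summary An [exceedance_summary()] for the same fit (optional;
#'   stratum proportions are skipped when absent).
#' @return Long tibble: `scenario`, `metric`, `mixture`, `stratum`, `value`.
#' @export
evaluate_fit <- function(fit, sim, grid_summary = NULL) {
  nm <- names(fit$quantized)
  fpm <- field_posterior_means(fit)
  wsum <- summarize_weights(fit)
  rows <- list()
  add <- function(metric, mixture, stratum, value) {
    rows[[length(rows) + 1L]] <<- tibble(
      scenario = sim$scenario, metric = metric, mixture = mixture,
      stratum = stratum, value = value
    )
  }
  spec <- scenario_spec(sim$scenario)
  for (j in seq_along(nm)) {
    add("coefficient_mse", nm[j], NA_character_,
      coefficient_mse(sim$truth[[paste0("true_mean_", nm[j])]],
        fpm[[paste0("beta_", nm[j])]]))
    est_w <- dplyr::filter(wsum, .data$mixture == nm[j])$mean
    we <- weights_error(sim$weights[[j]], est_w)
    add("weights_mse", nm[j], NA_character_, we$mse)
    add("weights_mae", nm[j], NA_character_, we$mae_mean)
    add("weights_mae_median", nm[j], NA_character_, we$mae_median)

    if (!is.null(grid_summary)) {
      surf <- spec$mixtures[[j]]$surface
      strata <- scenario_strata(surf$pattern, surf)
      cells <- dplyr::filter(grid_summary, .data$field == nm[j])
      props <- significant_proportion_by_stratum(cells, strata)
      for (i in seq_len(nrow(props))) {
        add("significant_proportion", nm[j], props$stratum[i], props$proportion[i])
      }
    }
  }
  if (length(nm) >= 2L) {
    add("coefficient_correlation", paste(nm[1], nm[2], sep = ":"), NA_character_,
      coefficient_correlation(fpm[[paste0("beta_", nm[1])]],
        fpm[[paste0("beta_", nm[2])]]))
  }
  dplyr::bind_rows(rows)
}

#' Aggregate per-dataset metric reports across a scenario
#'
#' Uses the study-level aggregation rule: the median across datasets for the
#' coefficient MSE, and the mean across datasets for weight errors,
#' significant-cell proportions and the inter-coefficient correlation.
#'
#' @param reports One or more [evaluate_fit()] tibbles (a list or a single
#'   row-bound tibble), all from the same scenario.
#' @return Tibble with `scenario`, `metric`, `mixture`, `stratum`, `value`,
#'   `D` (dataset count) and `aggregation` (`"median"` or `"mean"`).
#' @export
aggregate_reports <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  all <- dplyr::bind_rows(reports, .id = "dataset")
  if (dplyr::n_distinct(all$scenario) != 1L) {
    abort("All reports must come from the same scenario.")
  }
  all |>
    dplyr::group_by(.data$scenario, .data$metric, .data$mixture, .data$stratum) |>
    dplyr::summarise(
      D = dplyr::n_distinct(.data$dataset),
      aggregation = ifelse(.data$metric[1] == "coefficient_mse", "median", "mean"),
      value = if (.data$metric[1] == "coefficient_mse") median(.data$value) else mean(.data$value),
      .groups = "drop"
    ) |>
    dplyr::select("scenario", "metric", "mixture", "stratum", "value", "D", "aggregation")
}
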