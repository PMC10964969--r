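#' Tidy the scalar parameters of a fitted model
#'
#' One row per scalar parameter (importance weights, covariate effects,
#' spatial range, field and covariate scales): posterior mean, standard
#' deviation, central credible interval and Gelman-Rubin statistic.
#'
#' @param x An `svcmix_fit`.
#' @param conf.level Credible-interval level (default 0.95).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @method tidy svcmix_fit
#' @export
tidy.svcmix_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  long <- draws_long(x) |> dplyr::filter(.data$parameter != "loglik")
  out <- long |>
    dplyr::group_by(term = .data$parameter) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = sd(.data$value),
      conf.low = quantile(.data$value, a, names = FALSE),
      conf.high = quantile(.data$value, 1 - a, names = FALSE),
      .groups = "drop"
    )
  dplyr::left_join(out, dplyr::select(x$psrf, term = "parameter", rhat = "psrf"),
    by = "term")
}

#' One-row summary of a fitted model
#'
#' @param x An `svcmix_fit`.
#' @param ... Unused.
#' @return Tibble: subjects, mixtures, covariates, chains, retained draws,
#'   mean posterior log likelihood, max Gelman-Rubin statistic and the
#'   proportion of scalar parameters with PSRF < 1.1.
#' @method glance svcmix_fit
#' @export
glance.svcmix_fit <- function(x, ...) {
  tibble(
    n = x$data$n,
    n_mixtures = length(x$quantized),
    n_covariates = ncol(x$data$covariates),
    n_chains = x$config$n_chains,
    retained = x$config$retained,
    logLik = mean(pooled_draws(x, "loglik")),
    max_rhat = if (all(is.na(x$psrf$psrf))) NA_real_ else max(x$psrf$psrf, na.rm = TRUE),
    prop_converged = mean(x$psrf$converged, na.rm = TRUE)
  )
}

#' Plot posterior importance weights
#'
#' Posterior mean and 95% interval for every component, faceted by mixture.
#'
#' @param fit An `svcmix_fit`.
#' @return A ggplot object.
#' @export
plot_weights <- function(fit) {
  ws <- summarize_weights(fit)
  ggplot2::ggplot(ws, ggplot2::aes(
    x = stats::reorder(.data$component, .data$mean), y = .data$mean
  )) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::geom_hline(
      data = dplyr::count(ws, .data$mixture),
      mapping = ggplot2::aes(yintercept = 1 / .data$n), linetype = 2
    ) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~mixture, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "importance weight (posterior mean, 95% CrI)")
}

#' @method autoplot svcmix_fit
#' @export
autoplot.svcmix_fit <- function(object, ...) plot_weights(object)

#' Map a gridded exceedance summary
#'
#' Heatmap of the posterior-mean coefficient surface per field, with
#' significantly elevated / lowered cells outlined.
#'
#' @param object An [exceedance_summary()] tibble.
#' @param what Column to fill by (`"mean"`, `"p_above"`, `"or_mean"`, ...).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svcmix_grid_summary
#' @export
autoplot.svcmix_grid_summary <- function(object, what = "mean", ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[what]])) +
    ggplot2::geom_point(
      data = dplyr::filter(object, .data$flag != 0),
      mapping = ggplot2::aes(shape = factor(.data$flag)), size = 0.6
    ) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_shape_manual(values = c(`-1` = 25, `1` = 24), name = "flag") +
    ggplot2::facet_wrap(~field) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = what)
}
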