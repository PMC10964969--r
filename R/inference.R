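#' Exceedance probability of a coefficient
#'
#' The fraction of posterior draws strictly above (or below) the null value
#' of zero. Draws exactly equal to zero count toward neither direction.
#'
#' @param samples Numeric vector of posterior draws.
#' @param direction `"above"` or `"below"`.
#' @return Proportion in `[0, 1]`.
#' @export
exceedance_probability <- function(samples, direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (length(samples) < 1L) abort("Empty draw set.")
  if (direction == "above") mean(samples > 0) else mean(samples < 0)
}

#' Significance flags from exceedance probabilities
#'
#' A location is flagged `+1` if its probability of an elevated coefficient
#' exceeds the threshold, `-1` if the probability of a lowered coefficient
#' does, and `0` otherwise. The two cannot both fire for thresholds above
#' one half.
#'
#' @param p_above,p_below Exceedance probabilities (vectors of equal length).
#' @param threshold Significance threshold, default 0.95 (0.90 is the common
#'   alternative).
#' @return Integer vector of flags in `{-1, 0, 1}`.
#' @export
significance_flags <- function(p_above, p_below, threshold = 0.95) {
  stopifnot(length(p_above) == length(p_below), threshold > 0.5, threshold < 1)
  ifelse(p_above > threshold, 1L, ifelse(p_below > threshold, -1L, 0L))
}

#' Odds-ratio summary of coefficient draws
#'
#' Summarizes `exp(coef)` over the posterior draws: the mean is the mean of
#' the exponentiated draws (not the exponential of the mean), while the
#' percentiles commute with the transform.
#'
#' @param samples Posterior draws of a log-odds coefficient.
#' @param probs Percentiles to report.
#' @return One-row tibble: `or_mean`, and one `or_q<p>` column per percentile.
#' @export
odds_ratio_summary <- function(samples, probs = c(0.025, 0.5, 0.975)) {
  if (any(!is.finite(samples))) abort("Draws must be finite.")
  ors <- exp(samples)
  qs <- quantile(ors, probs, names = FALSE)
  out <- tibble(or_mean = mean(ors))
  out[paste0("or_q", format(probs * 100, trim = TRUE))] <- as.list(qs)
  out
}

#' Posterior summary of importance weights
#'
#' Componentwise posterior means (which sum to 1 by linearity) and credible
#' intervals for each mixture's weight simplex, ranked by mean weight.
#'
#' @param fit An `svcmix_fit`, or a draws matrix (K x C_j) for one mixture.
#' @param level Credible-interval level (default 0.95).
#' @return Tibble with `mixture`, `component`, `mean`, `lower`, `upper`,
#'   `rank` (1 = largest mean weight).
#' @export
summarize_weights <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  one <- function(draws, mixture, comp_names) {
    tibble(
      mixture = mixture,
      component = comp_names,
      mean = colMeans(draws),
      lower = apply(draws, 2, quantile, a, names = FALSE),
      upper = apply(draws, 2, quantile, 1 - a, names = FALSE)
    ) |>
      dplyr::arrange(dplyr::desc(.data$mean)) |>
      dplyr::mutate(rank = dplyr::row_number()) |>
      dplyr::arrange(match(.data$component, comp_names))
  }
  if (is.matrix(fit)) {
    return(one(fit, "mix1", colnames(fit) %||% paste0("c", seq_len(ncol(fit)))))
  }
  purrr::imap_dfr(fit$quantized, function(qm, nm) {
    j <- match(nm, names(fit$quantized))
    draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$omega[[j]]))
    one(draws, nm, colnames(qm) %||% paste0("c", seq_len(ncol(qm))))
  })
}

#' Exceedance summary of gridded (or subject-level) field draws
#'
#' Per cell and field: posterior mean, 95% interval, exceedance probabilities
#' in both directions, the significance flag at the stated threshold, and the
#' posterior mean odds ratio.
#'
#' @param grid_draws An `svcmix_grid` from [predict_grid()].
#' @param threshold Significance threshold (default 0.95).
#' @return Tibble of class `svcmix_grid_summary` with columns `field`, `x`,
#'   `y`, `mean`, `lower`, `upper`, `p_above`, `p_below`, `flag`, `or_mean`.
#' @export
exceedance_summary <- function(grid_draws, threshold = 0.95) {
  out <- purrr::imap_dfr(grid_draws$draws, function(dm, fname) {
    tibble(
      field = fname,
      x = grid_draws$grid$x, y = grid_draws$grid$y,
      mean = colMeans(dm),
      lower = apply(dm, 2, quantile, 0.025, names = FALSE),
      upper = apply(dm, 2, quantile, 0.975, names = FALSE),
      p_above = colMeans(dm > 0),
      p_below = colMeans(dm < 0),
      or_mean = colMeans(exp(dm))
    )
  })
  out$flag <- significance_flags(out$p_above, out$p_below, threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("svcmix_grid_summary", class(out))
  out
}

#' Write a map-ready gridded summary to CSV
#'
#' One row per cell per field. An optional coordinate jitter (privacy mode
#' for subject-level maps) perturbs only the exported coordinates, never the
#' summaries.
#'
#' @param summary An [exceedance_summary()] tibble.
#' @param path Output CSV path.
#' @param jitter_coords Standard deviation of an optional coordinate jitter
#'   (default 0 = none).
#' @return The exported tibble, invisibly.
#' @export
export_maps <- function(summary, path, jitter_coords = 0) {
  out <- as_tibble(summary)
  if (jitter_coords > 0) {
    out$x <- out$x + rnorm(nrow(out), 0, jitter_coords)
    out$y <- out$y + rnorm(nrow(out), 0, jitter_coords)
  }
  tryCatch(
    readr::write_csv(out, path),
    error = function(e) abort(paste0("Failed writing '", path, "'."), parent = e)
  )
  invisible(out)
}

#' Read a gridded summary written by [export_maps()]
#'
#' @param path CSV path.
#' @return The grid-summary tibble.
#' @export
read_maps <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("svcmix_grid_summary", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
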