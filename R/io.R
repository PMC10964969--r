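#' Write / read a mixture dataset CSV
#'
#' The on-disk schema is one row per subject: `id, x, y, outcome`, then the
#' component columns of each mixture (named `<mixture>_c<k>`), then any
#' covariate columns. A header is required; files are UTF-8.
#'
#' @param data Tibble in the schema above (e.g. `$data` of a simulated
#'   dataset).
#' @param path CSV path.
#' @return `write_mixture_data`: the input, invisibly. `read_mixture_data`:
#'   a tibble.
#' @export
write_mixture_data <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' @rdname write_mixture_data
#' @export
read_mixture_data <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Detect mixture component columns by naming convention
#'
#' Groups columns named `<prefix>_c<k>` by prefix, in first-appearance
#' order — the convention used by the simulation writer.
#'
#' @param data Data frame.
#' @return Named list of component column names per mixture.
#' @export
detect_mixtures <- function(data) {
  nm <- names(data)
  hits <- grep("^(.*)_c[0-9]+$", nm, value = TRUE)
  if (length(hits) == 0L) abort("No '<mixture>_c<k>' columns found.")
  pref <- sub("_c[0-9]+$", "", hits)
  split(hits, factor(pref, levels = unique(pref)))
}

#' Write retained scalar draws to long-format CSV
#'
#' One row per `(chain, iteration, parameter)` for every scalar parameter
#' (weights, covariate effects, spatial range, scales, log likelihood).
#' Latent field draws are kept in the binary fit container, not the CSV.
#'
#' @param fit An `svcmix_fit`.
#' @param path CSV path.
#' @return The long tibble, invisibly.
#' @export
write_draws <- function(fit, path) {
  long <- draws_long(fit)
  readr::write_csv(long, path)
  invisible(long)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      chain = readr::col_character(), iteration = readr::col_integer(),
      parameter = readr::col_character(), value = readr::col_double()
    ))
}

draws_long <- function(fit) {
  nm <- names(fit$quantized)
  purrr::imap_dfr(fit$chains, function(ch, chain) {
    K <- length(ch$rho)
    blocks <- list(tibble(parameter = "rho", iteration = seq_len(K), value = ch$rho),
      tibble(parameter = "loglik", iteration = seq_len(K), value = ch$loglik))
    for (j in seq_along(nm)) {
      om <- ch$omega[[j]]
      for (k in seq_len(ncol(om))) {
        blocks[[length(blocks) + 1L]] <- tibble(
          parameter = paste0("omega_", nm[j], "_", k),
          iteration = seq_len(K), value = om[, k])
      }
    }
    for (f in seq_len(ncol(ch$sigma_beta))) {
      blocks[[length(blocks) + 1L]] <- tibble(
        parameter = paste0("sigma_beta_", f),
        iteration = seq_len(K), value = ch$sigma_beta[, f])
    }
    for (b in seq_len(ncol(ch$theta))) {
      blocks[[length(blocks) + 1L]] <- tibble(
        parameter = paste0("theta_", b), iteration = seq_len(K), value = ch$theta[, b])
      blocks[[length(blocks) + 1L]] <- tibble(
        parameter = paste0("sigma_theta_", b),
        iteration = seq_len(K), value = ch$sigma_theta[, b])
    }
    dplyr::bind_rows(blocks) |> dplyr::mutate(chain = chain, .before = 1)
  })
}

#' Save / load a fit as a compact binary container
#'
#' Thin wrappers over [saveRDS()]/[readRDS()] for the full fit object
#' (including latent field draws), for hand-off between pipeline stages.
#'
#' @param fit An `svcmix_fit`.
#' @param path `.rds` path.
#' @return `read_fit`: the fit object.
#' @export
save_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_fit
#' @export
read_fit <- function(path) readRDS(path)

#' Write a metrics report as JSON and flat CSV
#'
#' The CSV is one row per scenario in a study-summary layout: columns
#' `<metric>[_<mixture>][_<stratum>]`.
#'
#' @param report An [aggregate_reports()] tibble.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return The wide one-row tibble, invisibly.
#' @export
write_metrics_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  wide <- report |>
    dplyr::mutate(name = paste0(
      .data$metric,
      ifelse(is.na(.data$mixture), "", paste0("_", .data$mixture)),
      ifelse(is.na(.data$stratum), "", paste0("_", .data$stratum))
    )) |>
    dplyr::select("scenario", "name", "value") |>
    tidyr::pivot_wider(names_from = "name", values_from = "value")
  if (!is.null(csv_path)) readr::write_csv(wide, csv_path)
  invisible(wide)
}
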