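#' Matern-3/2 spatial correlation
#'
#' Correlation between two locations a distance `d` apart under the Matern
#' family with smoothness 3/2 and unit marginal variance:
#' \deqn{\rho(d) = (1 + d/\rho)\exp(-d/\rho),}
#' where `rho` is the spatial range. The function equals 1 at `d = 0` and
#' decreases strictly with distance.
#'
#' @param d Non-negative distance(s); same units as the coordinates.
#' @param rho Spatial range parameter, `> 0`.
#' @return Numeric vector of correlations in `(0, 1]`.
#' @examples
#' matern32_correlation(c(0, 0.3, 3), rho = 0.3)
#' @export
matern32_correlation <- function(d, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    abort("`rho` must be a single finite value > 0.", class = "svcmix_invalid_parameter")
  }
  if (any(d < 0)) {
    abort("Distances must be non-negative.", class = "svcmix_invalid_parameter")
  }
  u <- d / rho
  (1 + u) * exp(-u)
}

#' Matern-3/2 correlation matrix for a set of locations
#'
#' Builds the n x n spatial correlation matrix with entry (j, k) equal to
#' [matern32_correlation()] of the Euclidean distance between locations j and
#' k, plus a small diagonal jitter for numerical stability of the Cholesky
#' factorization.
#'
#' @param locations Numeric matrix or data frame with two columns (x, y).
#' @param rho Spatial range, `> 0`.
#' @param jitter Non-negative value added to the diagonal (default `1e-6`).
#' @return A symmetric positive-definite matrix with unit diagonal before
#'   jitter.
#' @export
matern_correlation_matrix <- function(locations, rho, jitter = 1e-6) {
  locations <- as_location_matrix(locations)
  if (jitter < 0) abort("`jitter` must be non-negative.", class = "svcmix_invalid_parameter")
  D <- as.matrix(dist(locations))
  if (nrow(locations) > 1L && jitter == 0) {
    off <- D[upper.tri(D)]
    if (any(off == 0)) {
      abort(
        "Duplicate locations give a singular correlation matrix; use a nonzero `jitter`.",
        class = "svcmix_singular_geometry"
      )
    }
  }
  Omega <- matern32_correlation(D, rho)
  dim(Omega) <- dim(D)
  diag(Omega) <- 1 + jitter
  Omega
}

#' Range of pairwise inter-point distances
#'
#' Returns the smallest and largest Euclidean distance over distinct pairs of
#' locations. These bounds define the support of the uniform prior on the
#' spatial range parameter.
#'
#' @inheritParams matern_correlation_matrix
#' @return Named numeric vector `c(d_min, d_max)` with `0 < d_min <= d_max`.
#' @export
pairwise_distance_bounds <- function(locations) {
  locations <- as_location_matrix(locations)
  if (nrow(locations) < 2L) {
    abort("At least two locations are required.", class = "svcmix_degenerate_geometry")
  }
  d <- as.numeric(dist(locations))
  d <- d[d > 0]
  if (length(d) == 0L) {
    abort("All locations are identical; distance bounds are degenerate.",
      class = "svcmix_degenerate_geometry")
  }
  c(d_min = min(d), d_max = max(d))
}

#' One joint conditional (kriging) draw of a Gaussian field
#'
#' Given the values of a mean-zero Gaussian-process field at observed
#' locations, draws the field jointly at new locations from the conditional
#' multivariate normal. The field has covariance `(1/tau) * Omega` with
#' `Omega` the Matern-3/2 correlation matrix, so the conditional mean is
#' `S_no S_oo^-1 f_obs` and the conditional covariance
#' `(1/tau) (S_nn - S_no S_oo^-1 S_on)` (correlation-scale blocks `S`).
#'
#' @param field_obs Field values at the observed locations (length n).
#' @param obs_locs n x 2 matrix of observed locations.
#' @param new_locs m x 2 matrix of prediction locations.
#' @param rho Spatial range.
#' @param tau Field precision (`> 0`); marginal variance is `1/tau`.
#' @param jitter Diagonal jitter for both correlation blocks.
#' @return Numeric vector of length m: one joint draw. With `new_locs` equal
#'   to `obs_locs` and `jitter = 0` the draw reproduces `field_obs`.
#' @export
conditional_field_draw <- function(field_obs, obs_locs, new_locs, rho, tau,
                                   jitter = 1e-6) {
  obs_locs <- as_location_matrix(obs_locs)
  new_locs <- as_location_matrix(new_locs)
  stopifnot(length(field_obs) == nrow(obs_locs), tau > 0)
  S_oo <- matern_correlation_matrix(obs_locs, rho, jitter)
  D_no <- cross_distance(new_locs, obs_locs)
  S_no <- matern32_correlation(D_no, rho)
  dim(S_no) <- dim(D_no)
  S_nn <- matern_correlation_matrix(new_locs, rho, jitter)

  L <- tryCatch(t(chol(S_oo)), error = function(e) {
    abort("Observed-location correlation matrix is not positive definite after jitter.",
      class = "svcmix_numerical_error", parent = e)
  })
  # A = S_no S_oo^-1 via triangular solves against the Cholesky factor
  V <- forwardsolve(L, t(S_no))              # n x m
  w <- forwardsolve(L, field_obs)            # n
  cond_mean <- drop(crossprod(V, w))
  cond_corr <- S_nn - crossprod(V)
  cond_corr <- (cond_corr + t(cond_corr)) / 2

  Lc <- tryCatch(t(chol(cond_corr)), error = function(e) NULL)
  if (is.null(Lc)) {
    # Near-singular conditional (e.g. prediction at observed sites): clamp
    # negative eigenvalues to zero rather than fail.
    eg <- eigen(cond_corr, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    if (any(!is.finite(ev))) {
      abort("Conditional covariance is not factorizable; increase `jitter`.",
        class = "svcmix_numerical_error")
    }
    Lc <- eg$vectors %*% diag(sqrt(ev), nrow = length(ev))
  }
  cond_mean + drop(Lc %*% rnorm(nrow(new_locs))) / sqrt(tau)
}

#' Regular grid of cell centers over a bounding box
#'
#' @param grid_size Number of cells per side (default 30, i.e. 900 cells).
#' @param bbox Numeric vector `c(xmin, xmax, ymin, ymax)`; default unit square.
#' @return Tibble with columns `x`, `y` (cell centers, row-major by y then x).
#' @export
grid_centers <- function(grid_size = 30, bbox = c(0, 1, 0, 1)) {
  stopifnot(grid_size >= 1, length(bbox) == 4, bbox[2] > bbox[1], bbox[4] > bbox[3])
  gx <- bbox[1] + (seq_len(grid_size) - 0.5) / grid_size * (bbox[2] - bbox[1])
  gy <- bbox[3] + (seq_len(grid_size) - 0.5) / grid_size * (bbox[4] - bbox[3])
  tidyr::expand_grid(y = gy, x = gx)[, c("x", "y")]
}

# --- internal helpers --------------------------------------------------------

as_location_matrix <- function(locations) {
  if (is.data.frame(locations)) locations <- as.matrix(locations[, 1:2])
  if (is.null(dim(locations))) locations <- matrix(locations, ncol = 2)
  locations <- unname(as.matrix(locations))
  if (ncol(locations) != 2L || !is.numeric(locations) || any(!is.finite(locations))) {
    abort("Locations must be a finite numeric n x 2 matrix.", class = "svcmix_invalid_parameter")
  }
  locations
}

cross_distance <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}
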