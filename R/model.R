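#' Declare the mixture structure of an analysis
#'
#' A mixture design names the component columns of each exposure mixture and
#' the number of quantile bins used to score raw concentrations.
#'
#' @param mixtures Named list; each element is a character vector of component
#'   column names for one mixture.
#' @param q Number of quantile bins (default 4, i.e. quartile scores 0..3).
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(mixtures, q = 4) {
  if (!is.list(mixtures) || length(mixtures) < 1L) {
    abort("`mixtures` must be a non-empty list of component-name vectors.")
  }
  if (is.null(names(mixtures)) || any(names(mixtures) == "")) {
    names(mixtures) <- paste0("mix", seq_along(mixtures))
  }
  if (!all(vapply(mixtures, function(m) is.character(m) && length(m) >= 1L, logical(1)))) {
    abort("Each mixture must be a character vector with at least one component.")
  }
  if (q < 2 || q != round(q)) abort("`q` must be an integer >= 2.")
  structure(list(mixtures = mixtures, q = as.integer(q)), class = "mixture_design")
}

#' Assemble and validate a case-control mixture dataset
#'
#' Checks a per-subject data frame for the pieces the model needs: 2-D
#' coordinates, a strictly binary outcome, raw component concentrations for
#' each mixture, and optional adjustment covariates. Missing values are
#' rejected, not imputed.
#'
#' @param data Data frame with one row per subject.
#' @param design A [mixture_design()], or a named list of component columns
#'   (then `q` applies).
#' @param covariates Character vector of covariate column names (optional).
#' @param coords Names of the coordinate columns (default `c("x", "y")`).
#' @param outcome Name of the binary outcome column (default `"outcome"`).
#' @param id Name of the subject-id column, or `NULL` to use row numbers.
#' @param q Quantile bins, used when `design` is a plain list.
#' @return An object of class `svcmix_data`: validated blocks plus the design.
#' @export
mixture_data <- function(data, design, covariates = NULL,
                         coords = c("x", "y"), outcome = "outcome",
                         id = NULL, q = 4) {
  data <- as_tibble(data)
  if (!inherits(design, "mixture_design")) design <- mixture_design(design, q = q)
  needed <- c(coords, outcome, unlist(design$mixtures), covariates, id)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Columns not found in `data`: ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 1L) abort("`data` has no rows.")
  blocks <- data[, needed]
  if (anyNA(blocks)) abort("Missing values are not supported; supply complete cases.")

  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) abort("`outcome` must be strictly binary (0/1).")

  locations <- as_location_matrix(data[, coords])
  components <- lapply(design$mixtures, function(cols) {
    m <- as.matrix(data[, cols, drop = FALSE])
    if (!is.numeric(m)) abort("Component columns must be numeric.")
    m
  })
  covmat <- if (length(covariates) > 0L) {
    x <- as.matrix(data[, covariates, drop = FALSE])
    if (!is.numeric(x)) abort("Covariate columns must be numeric.")
    x
  } else {
    matrix(0, n, 0)
  }
  ids <- if (is.null(id)) seq_len(n) else data[[id]]
  structure(
    list(
      ids = ids, locations = locations, outcome = as.numeric(y),
      components = components, covariates = covmat, design = design,
      n = n
    ),
    class = "svcmix_data"
  )
}

#' @export
print.svcmix_data <- function(x, ...) {
  cj <- vapply(x$components, ncol, integer(1))
  cat("<svcmix_data> ", x$n, " subjects, ", length(cj), " mixture(s) [",
    paste(cj, collapse = ", "), " components], ",
    ncol(x$covariates), " covariate(s); ",
    sum(x$outcome), " cases / ", x$n - sum(x$outcome), " controls\n",
    sep = ""
  )
  invisible(x)
}

#' Score raw concentrations into quantile bins
#'
#' Each column is scored 0..q-1 by its in-sample quantile breaks (the q-1
#' interior sample quantiles), using right-closed intervals so ties share the
#' score of their interval. Quantile scoring tames collinearity between
#' correlated components and removes scale differences; scores are invariant
#' to strictly increasing transforms of a column.
#'
#' @param x Numeric matrix/data frame of raw values, or an `svcmix_data`
#'   object (then every mixture block is scored with the design's `q`).
#' @param q Number of bins.
#' @return Integer matrix of scores (or list of matrices for `svcmix_data`).
#' @export
quantize_components <- function(x, q = 4) {
  if (inherits(x, "svcmix_data")) {
    return(lapply(x$components, quantize_components, q = x$design$q))
  }
  x <- as.matrix(x)
  if (nrow(x) < q) abort("Need at least `q` rows to form quantile bins.")
  nm <- colnames(x)
  out <- vapply(seq_len(ncol(x)), function(j) {
    col <- x[, j]
    breaks <- quantile(col, probs = seq_len(q - 1) / q, names = FALSE)
    if (length(unique(col)) == 1L) {
      abort(paste0(
        "Column ", if (is.null(nm)) j else paste0("'", nm[j], "'"),
        " is constant; quantile scores are undefined."
      ), class = "svcmix_degenerate_column")
    }
    # right-closed: values <= the k-th interior quantile stay in bin k-1
    rowSums(outer(col, breaks, ">"))
  }, numeric(nrow(x)))
  out <- matrix(as.integer(out), nrow = nrow(x), dimnames = list(NULL, nm))
  out
}

#' Weighted group index
#'
#' The group index of mixture j for one subject is the weighted sum
#' `sum_k omega_jk * q_ijk` of its quantile scores, with the importance
#' weights on the simplex. Accepts a score vector or an n x C_j score matrix.
#'
#' @param q_scores Numeric vector (one subject) or matrix (n subjects).
#' @param omega Simplex weight vector of matching length.
#' @return Scalar or n-vector of indices in `[0, q - 1]`.
#' @export
group_index <- function(q_scores, omega) {
  omega <- check_simplex(omega)
  if (is.matrix(q_scores)) {
    if (ncol(q_scores) != length(omega)) abort("Score/weight dimension mismatch.")
    return(drop(q_scores %*% omega))
  }
  if (length(q_scores) != length(omega)) abort("Score/weight dimension mismatch.")
  sum(q_scores * omega)
}

#' Parameter state constructor
#'
#' Bundles one state of every unknown in the model: the spatial intercept
#' field, the n x C matrix of mixture-effect fields, the per-mixture weight
#' simplices, covariate effects, the spatial range, per-field precisions and
#' per-covariate prior scales.
#'
#' @param beta0 Length-n intercept field (a scalar is recycled).
#' @param beta n x C matrix of mixture coefficient fields.
#' @param omega List of C simplex weight vectors.
#' @param theta Covariate effects (length B, possibly 0).
#' @param rho Spatial range.
#' @param tau_beta Field precisions, length C + 1 (intercept first).
#' @param sigma_theta Prior scales of the covariate effects (length B).
#' @return A list of class `svcmix_params`.
#' @export
svcmix_params <- function(beta0, beta, omega, theta = numeric(0), rho,
                          tau_beta, sigma_theta = rep(1, length(theta))) {
  beta <- as.matrix(beta)
  n <- nrow(beta)
  if (length(beta0) == 1L) beta0 <- rep(beta0, n)
  stopifnot(length(beta0) == n, length(omega) == ncol(beta),
    length(tau_beta) == ncol(beta) + 1L, all(tau_beta > 0), rho > 0,
    length(sigma_theta) == length(theta))
  omega <- lapply(omega, check_simplex)
  structure(list(beta0 = beta0, beta = beta, omega = omega, theta = theta,
    rho = rho, tau_beta = tau_beta, sigma_theta = sigma_theta),
  class = "svcmix_params")
}

#' Linear predictor of the spatially varying mixture model
#'
#' `eta_i = beta_i0 + sum_j beta_ij * index_ij + sum_b theta_b x_ib`, where
#' `index_ij` is the [group_index()] of mixture j for subject i. The case
#' probability is `plogis(eta)`.
#'
#' @param params An [svcmix_params()] state.
#' @param quantized List of quantile-score matrices (one per mixture).
#' @param covariates n x B covariate matrix (or `NULL`).
#' @return Numeric n-vector `eta`.
#' @export
linear_predictor <- function(params, quantized, covariates = NULL) {
  eta <- params$beta0
  for (j in seq_along(quantized)) {
    eta <- eta + params$beta[, j] * group_index(quantized[[j]], params$omega[[j]])
  }
  if (!is.null(covariates) && ncol(covariates) > 0L) {
    eta <- eta + drop(as.matrix(covariates) %*% params$theta)
  }
  eta
}

#' Bernoulli log likelihood
#'
#' `sum_i [y_i log p_i + (1 - y_i) log(1 - p_i)]` with `p = plogis(eta)`,
#' evaluated in the numerically stable log-sigmoid form.
#'
#' @param params,quantized,covariates As in [linear_predictor()].
#' @param outcome Binary n-vector.
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(params, outcome, quantized, covariates = NULL) {
  eta <- linear_predictor(params, quantized, covariates)
  if (any(!is.finite(eta))) abort("Non-finite linear predictor.", class = "svcmix_numerical_error")
  sum(outcome * eta - log1p_exp(eta))
}

#' Prior specification
#'
#' @param alpha Dirichlet concentration for the weights: either a single
#'   value recycled within each mixture (default 1, non-informative) or a
#'   list of per-mixture vectors.
#' @param sigma_upper Upper bound of the Uniform(0, upper) priors on the
#'   field scales `sigma_beta` (with `tau = sigma_beta^-2`) and on the
#'   covariate prior scales (default 10).
#' @param rho_bounds Support of the uniform prior on the spatial range;
#'   defaults to the observed [pairwise_distance_bounds()] when fitting.
#' @return A list of class `svcmix_priors`.
#' @export
prior_spec <- function(alpha = 1, sigma_upper = 10, rho_bounds = NULL) {
  stopifnot(sigma_upper > 0)
  if (is.numeric(alpha) && any(alpha <= 0)) abort("`alpha` entries must be > 0.")
  structure(list(alpha = alpha, sigma_upper = sigma_upper, rho_bounds = rho_bounds),
    class = "svcmix_priors")
}

resolve_alpha <- function(priors, design) {
  C_j <- vapply(design$mixtures, length, integer(1))
  if (is.list(priors$alpha)) {
    stopifnot(length(priors$alpha) == length(C_j))
    return(purrr::map2(priors$alpha, C_j, function(a, k) {
      if (length(a) == 1L) rep(a, k) else {stopifnot(length(a) == k); a}
    }))
  }
  lapply(C_j, function(k) rep(priors$alpha, length.out = k))
}

#' Joint log prior density
#'
#' Sum of: a mean-zero multivariate-normal log density for each spatial field
#' (covariance `(1/tau) * Omega` with Matern-3/2 correlation `Omega`); a
#' Dirichlet log density per weight simplex; uniform log densities for the
#' spatial range and every scale parameter; and normal log densities for the
#' covariate effects. Support violations return `-Inf` rather than erroring.
#'
#' @param params An [svcmix_params()] state.
#' @param priors A [prior_spec()] with non-null `rho_bounds`.
#' @param locations n x 2 coordinates of the subjects.
#' @param design The [mixture_design()] (for the Dirichlet dimensions).
#' @param jitter Diagonal jitter for the correlation matrix.
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, priors, locations, design, jitter = 1e-6) {
  rb <- priors$rho_bounds
  if (is.null(rb)) abort("`priors$rho_bounds` must be set (see pairwise_distance_bounds()).")
  if (params$rho < rb[1] || params$rho > rb[2]) return(-Inf)
  sigma_beta <- 1 / sqrt(params$tau_beta)
  if (any(sigma_beta <= 0 | sigma_beta >= priors$sigma_upper)) return(-Inf)
  if (length(params$sigma_theta) &&
      any(params$sigma_theta <= 0 | params$sigma_theta >= priors$sigma_upper)) {
    return(-Inf)
  }

  locations <- as_location_matrix(locations)
  n <- nrow(locations)
  Omega <- matern_correlation_matrix(locations, params$rho, jitter)
  L <- tryCatch(t(chol(Omega)), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  logdet <- 2 * sum(log(diag(L)))
  mvn_ld <- function(f, tau) {
    qf <- sum(forwardsolve(L, f)^2)
    -0.5 * n * log(2 * pi) + 0.5 * n * log(tau) - 0.5 * logdet - 0.5 * tau * qf
  }
  lp <- mvn_ld(params$beta0, params$tau_beta[1])
  for (j in seq_len(ncol(params$beta))) {
    lp <- lp + mvn_ld(params$beta[, j], params$tau_beta[j + 1])
  }

  alpha <- resolve_alpha(priors, design)
  for (j in seq_along(params$omega)) {
    w <- params$omega[[j]]
    if (any(w <= 0) || abs(sum(w) - 1) > 1e-9) return(-Inf)
    a <- alpha[[j]]
    lp <- lp + lgamma(sum(a)) - sum(lgamma(a)) + sum((a - 1) * log(w))
  }

  # uniform densities on their supports
  lp <- lp - log(rb[2] - rb[1])
  lp <- lp - (length(sigma_beta) + length(params$sigma_theta)) * log(priors$sigma_upper)
  if (length(params$theta)) {
    lp <- lp + sum(stats::dnorm(params$theta, 0, params$sigma_theta, log = TRUE))
  }
  lp
}

#' Joint log posterior (up to the model constant)
#'
#' `log_likelihood + log_prior`; `-Inf` from the prior propagates.
#'
#' @inheritParams log_prior
#' @param data An `svcmix_data` object.
#' @param quantized Quantile scores from [quantize_components()].
#' @return Scalar log posterior density.
#' @export
log_posterior <- function(params, data, quantized, priors, jitter = 1e-6) {
  lp <- log_prior(params, priors, data$locations, data$design, jitter = jitter)
  if (!is.finite(lp)) return(lp)
  lp + log_likelihood(params, data$outcome, quantized, data$covariates)
}

# --- internal ---------------------------------------------------------------

check_simplex <- function(omega, tol = 1e-9) {
  if (any(omega < 0) || abs(sum(omega) - 1) > tol) {
    abort("Weights must be non-negative and sum to 1.", class = "svcmix_invalid_parameter")
  }
  omega
}

log1p_exp <- function(x) {
  out <- numeric(length(x))
  hi <- x > 35
  lo <- x < -35
  mid <- !hi & !lo
  out[hi] <- x[hi]
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out
}
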