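#' Kullback-Leibler divergence between two univariate Gaussians
#'
#' Closed form `KL(X||Y) = (1/2) [ s2x/s2y - 1 + (mx-my)^2/s2y + ln(s2y/s2x) ]`
#' for `X ~ N(mx, s2x)` and `Y ~ N(my, s2y)`.
#'
#' @param mean_x,mean_y means.
#' @param var_x,var_y variances (strictly positive).
#' @return Nonnegative scalar divergence.
#' @examples
#' kl_gaussian_univariate(0, 1, 1, 1) # 0.5
#' @export
kl_gaussian_univariate <- function(mean_x, var_x, mean_y, var_y) {
  if (!is.finite(var_x) || !is.finite(var_y) || var_x <= 0 || var_y <= 0) {
    stop_invalid_parameter("variances must be strictly positive")
  }
  kl <- 0.5 * (var_x / var_y - 1 + (mean_x - mean_y)^2 / var_y +
    log(var_y / var_x))
  clamp_kl(kl)
}

# Tiny negatives are floating-point noise and are clamped to zero; anything
# materially below zero indicates a bug in the caller's inputs.
clamp_kl <- function(kl) {
  if (kl < -1e-8) {
    stop_internal(sprintf("computed KL divergence %g is materially negative", kl))
  }
  max(kl, 0)
}

# Cholesky factor with an optional one-shot jitter repair. `stabilize = FALSE`
# (the default) prefers an explicit error over a silent repair.
chol_or_stop <- function(sigma, which, stabilize = FALSE, delta = 1e-8) {
  r <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(r) && stabilize) {
    jitter <- delta * mean(diag(sigma)) * diag(nrow(sigma))
    r <- tryCatch(chol(sigma + jitter), error = function(e) NULL)
  }
  if (is.null(r)) {
    stop_not_positive_definite(which)
  }
  r
}

# Shared numerical core, Eq-(2)-style closed form evaluated through
# triangular factorizations: no explicit inverse, log-determinants read off
# the Cholesky diagonals.
kl_gauss_core <- function(mean_x, cov_x, mean_y, cov_y,
                          names = c("cov_x", "cov_y"), stabilize = FALSE) {
  p <- length(mean_x)
  rx <- chol_or_stop(cov_x, names[1], stabilize)
  ry <- chol_or_stop(cov_y, names[2], stabilize)
  delta <- mean_y - mean_x
  # tr(Sy^-1 Sx) = || Ry^-T Rx^T ||_F^2 ; quad form via one triangular solve.
  m <- backsolve(ry, t(rx), transpose = TRUE)
  trace_term <- sum(m * m)
  z <- backsolve(ry, delta, transpose = TRUE)
  quad <- sum(z * z)
  logdet_y <- 2 * sum(log(diag(ry)))
  logdet_x <- 2 * sum(log(diag(rx)))
  clamp_kl(0.5 * (trace_term - p + quad + logdet_y - logdet_x))
}

#' Kullback-Leibler divergence between two Gaussian processes on a grid
#'
#' Evaluates the closed-form divergence between the `p`-variate Gaussian
#' restrictions of two processes to their (common) grid:
#' `KL = (1/2) [ tr(Sy^-1 Sx) - p + d' Sy^-1 d + ln det Sy - ln det Sx ]`
#' with `d = mu_y - mu_x`. The second argument plays the role of the
#' weighting (inverted) distribution throughout the package.
#'
#' @param params_x,params_y [gaussian_grid_params()] on the same grid.
#' @param stabilize logical; if `TRUE`, a jitter `delta * mean(diag) * I`
#'   (`delta = 1e-8`) is added once on factorization failure instead of
#'   erroring. Off by default.
#' @return Nonnegative scalar divergence.
#' @export
kl_gaussian_multivariate <- function(params_x, params_y, stabilize = FALSE) {
  assert_params(params_x)
  assert_params(params_y)
  if (!same_grid(params_x$grid, params_y$grid)) {
    stop_invalid_parameter("parameter sets must share the same grid")
  }
  kl_gauss_core(
    params_x$mean, params_x$cov, params_y$mean, params_y$cov,
    names = c("cov_x", "cov_y"), stabilize = stabilize
  )
}

#' Local Kullback-Leibler divergence on a subset of the grid
#'
#' Restricts both parameter sets to the given grid indices (mean sub-vector
#' and principal covariance sub-matrix) and evaluates
#' [kl_gaussian_multivariate()] on the restrictions. A singleton index set is
#' delegated to [kl_gaussian_univariate()].
#'
#' @inheritParams kl_gaussian_multivariate
#' @param indices nonempty, duplicate-free vector of grid indices in `1..p`.
#' @return Nonnegative scalar divergence of the restricted processes.
#' @export
kl_local <- function(params_x, params_y, indices, stabilize = FALSE) {
  assert_params(params_x)
  assert_params(params_y)
  if (!same_grid(params_x$grid, params_y$grid)) {
    stop_invalid_parameter("parameter sets must share the same grid")
  }
  indices <- check_indices(indices, params_x$grid$p)
  if (length(indices) == 1L) {
    vx <- params_x$cov[indices, indices]
    vy <- params_y$cov[indices, indices]
    if (vx <= 0) stop_not_positive_definite("cov_x")
    if (vy <= 0) stop_not_positive_definite("cov_y")
    return(kl_gaussian_univariate(
      params_x$mean[indices], vx, params_y$mean[indices], vy
    ))
  }
  kl_gauss_core(
    params_x$mean[indices],
    params_x$cov[indices, indices, drop = FALSE],
    params_y$mean[indices],
    params_y$cov[indices, indices, drop = FALSE],
    names = c("cov_x", "cov_y"), stabilize = stabilize
  )
}

#' Symmetrized local Kullback-Leibler divergence
#'
#' The average `[KL_A(X||Y) + KL_A(Y||X)] / 2`; symmetric in its first two
#' arguments. The directed divergence is the package default everywhere (it
#' is what the interval selector optimizes); symmetrization is offered as an
#' option.
#'
#' @inheritParams kl_local
#' @return Nonnegative scalar.
#' @export
kl_symmetrized <- function(params_x, params_y, indices = NULL, stabilize = FALSE) {
  if (is.null(indices)) {
    assert_params(params_x)
    indices <- seq_len(params_x$grid$p)
  }
  0.5 * kl_local(params_x, params_y, indices, stabilize) +
    0.5 * kl_local(params_y, params_x, indices, stabilize)
}
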