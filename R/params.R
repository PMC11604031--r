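#' Gaussian parameters on a grid
#'
#' Mean vector and covariance matrix of the finite-dimensional restriction of
#' a Gaussian process to a [grid_domain()]. Symmetry of the covariance is
#' required (relative tolerance `1e-8`); positive definiteness is *not*
#' enforced at construction time because rank-deficient population
#' covariances are legitimate inputs to the shrinkage machinery - any
#' factorization failure surfaces as a `kld_not_positive_definite` error at
#' the point of use.
#'
#' @param grid a [grid_domain()].
#' @param mean numeric vector of length `grid$p`.
#' @param cov symmetric `p x p` numeric matrix.
#' @return An object of class `gaussian_grid_params`.
#' @export
gaussian_grid_params <- function(grid, mean, cov) {
  assert_grid(grid)
  mean <- as.numeric(mean)
  if (length(mean) != grid$p) {
    stop_invalid_parameter("'mean' length must equal grid$p")
  }
  if (!is.matrix(cov) || nrow(cov) != grid$p || ncol(cov) != grid$p) {
    stop_invalid_parameter("'cov' must be a p x p matrix matching the grid")
  }
  scale <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > 1e-8 * scale) {
    stop_invalid_parameter("'cov' is not symmetric within relative tolerance 1e-8")
  }
  cov <- (cov + t(cov)) / 2
  structure(
    list(grid = grid, mean = mean, cov = cov),
    class = "gaussian_grid_params"
  )
}

#' @export
print.gaussian_grid_params <- function(x, ...) {
  cat(sprintf(
    "<gaussian_grid_params> p = %d on [%g, %g]; mean range [%g, %g]\n",
    x$grid$p, x$grid$t_min, x$grid$t_max, min(x$mean), max(x$mean)
  ))
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "gaussian_grid_params")) {
    stop_invalid_input("expected a 'gaussian_grid_params' object")
  }
  invisible(params)
}

# Principal restriction of the parameters to a set of grid indices.
restrict_params <- function(params, indices) {
  indices <- check_indices(indices, params$grid$p)
  sub_grid <- grid_domain(
    length(indices),
    t_min = params$grid$t_min,
    t_max = params$grid$t_max,
    points = params$grid$points[indices]
  )
  gaussian_grid_params(
    sub_grid,
    params$mean[indices],
    params$cov[indices, indices, drop = FALSE]
  )
}

check_indices <- function(indices, p) {
  if (length(indices) == 0L) {
    stop_invalid_parameter("index set must be nonempty")
  }
  if (any(!is.finite(indices)) || any(indices != round(indices))) {
    stop_invalid_parameter("indices must be integers")
  }
  indices <- as.integer(indices)
  if (any(indices < 1L) || any(indices > p)) {
    stop_invalid_parameter(sprintf("indices must lie in 1..%d", p))
  }
  if (anyDuplicated(indices)) {
    stop_invalid_parameter("indices must be duplicate-free")
  }
  sort(indices)
}
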