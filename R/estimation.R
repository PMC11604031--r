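#' A set of curves observed on a common grid
#'
#' Container for `n` curves sampled on the same [grid_domain()]: an `n x p`
#' value matrix plus an optional group label.
#'
#' @param values numeric `n x p` matrix, one row per curve.
#' @param grid a [grid_domain()] with `p = ncol(values)`.
#' @param label optional group identifier (scalar).
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(values, grid, label = NULL) {
  assert_grid(grid)
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid_input("'values' must be a numeric matrix without missing entries")
  }
  if (ncol(values) != grid$p) {
    stop_invalid_input("'values' must have grid$p columns")
  }
  if (nrow(values) < 1L) {
    stop_invalid_input("'values' must contain at least one curve")
  }
  structure(
    list(values = values, grid = grid, label = label),
    class = "curve_set"
  )
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf(
    "<curve_set>%s n = %d curves on %d grid points over [%g, %g]\n",
    if (is.null(x$label)) "" else sprintf(" '%s':", x$label),
    nrow(x$values), x$grid$p, x$grid$t_min, x$grid$t_max
  ))
  invisible(x)
}

assert_curve_set <- function(x) {
  if (!inherits(x, "curve_set")) {
    stop_invalid_input("expected a 'curve_set' object")
  }
  invisible(x)
}

#' Maximum-likelihood Gaussian parameters of a curve sample
#'
#' Sample mean vector and maximum-likelihood covariance (divisor `n`, not
#' `n - 1`) of the curves, returned as [gaussian_grid_params()]. With `p`
#' large relative to `n` the MLE covariance is rank-deficient; combine with
#' [shrink_covariance()] before inverting.
#'
#' @param curves a [curve_set()] with `n >= 2`.
#' @return A [gaussian_grid_params()] on the curves' grid.
#' @export
estimate_gaussian_params <- function(curves) {
  assert_curve_set(curves)
  n <- nrow(curves$values)
  if (n < 2L) {
    stop_insufficient_sample("at least 2 curves are required to estimate a covariance")
  }
  mu <- colMeans(curves$values)
  centred <- sweep(curves$values, 2L, mu)
  sigma <- crossprod(centred) / n
  gaussian_grid_params(curves$grid, mu, sigma)
}

#' Shrink a covariance matrix toward its diagonal
#'
#' Convex combination `eta * cov + (1 - eta) * diag(cov)`. The diagonal is
#' unchanged for every `eta`; `eta = 1` returns the input, `eta = 0` the
#' diagonal matrix of variances. For any `eta < 1` the result is positive
#' definite whenever the diagonal is strictly positive, which is what makes
#' rank-deficient sample covariances usable in the divergence.
#'
#' @param cov symmetric matrix with strictly positive diagonal.
#' @param eta shrinkage weight in `[0, 1]`.
#' @return Shrunken covariance matrix.
#' @examples
#' shrink_covariance(matrix(c(2, 1, 1, 2), 2), 0.5)
#' @export
shrink_covariance <- function(cov, eta) {
  if (length(eta) != 1L || !is.finite(eta) || eta < 0 || eta > 1) {
    stop_invalid_parameter("'eta' must lie in [0, 1]")
  }
  if (!is.matrix(cov) || nrow(cov) != ncol(cov)) {
    stop_invalid_parameter("'cov' must be a square matrix")
  }
  d <- diag(cov)
  if (any(d <= 0)) {
    kld_stop(
      "covariance diagonal must be strictly positive to shrink toward it",
      "kld_degenerate_covariance"
    )
  }
  eta * cov + (1 - eta) * diag(d, nrow = nrow(cov))
}

#' Shrinkage configuration
#'
#' Bundles how the shrinkage weight `eta` is chosen: either a fixed value in
#' `[0, 1]` or `"cv"` for K-fold cross-validation over a candidate grid,
#' scored by held-out Gaussian log-density (see [select_shrinkage_cv()]).
#'
#' @param eta fixed numeric value in `[0, 1]`, or `"cv"`.
#' @param eta_grid candidate values used when `eta = "cv"`.
#' @param folds number of cross-validation folds (`>= 2`).
#' @param seed integer seed for the fold assignment (optional).
#' @return An object of class `shrinkage_config`.
#' @export
shrinkage_config <- function(eta = "cv", eta_grid = seq(0, 1, by = 0.1),
                             folds = 5L, seed = NULL) {
  if (is.numeric(eta)) {
    if (length(eta) != 1L || !is.finite(eta) || eta < 0 || eta > 1) {
      stop_invalid_parameter("fixed 'eta' must lie in [0, 1]")
    }
  } else if (!identical(eta, "cv")) {
    stop_invalid_parameter("'eta' must be a number in [0, 1] or \"cv\"")
  }
  if (length(eta_grid) < 1L || any(eta_grid < 0) || any(eta_grid > 1)) {
    stop_invalid_parameter("'eta_grid' must be a nonempty subset of [0, 1]")
  }
  if (folds < 2L) {
    stop_invalid_parameter("'folds' must be at least 2")
  }
  structure(
    list(
      eta = eta, eta_grid = sort(unique(as.numeric(eta_grid))),
      folds = as.integer(folds), seed = seed
    ),
    class = "shrinkage_config"
  )
}

assert_shrinkage <- function(config) {
  if (!inherits(config, "shrinkage_config")) {
    stop_invalid_input("expected a 'shrinkage_config' object")
  }
  invisible(config)
}

# Per-curve Gaussian log-density of the rows of `x` under N(mu, sigma),
# via one Cholesky factorization. Returns -Inf when sigma is not PD.
gaussian_logdensity <- function(x, mu, sigma) {
  r <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(r)) {
    return(rep(-Inf, nrow(x)))
  }
  p <- ncol(x)
  centred <- sweep(x, 2L, mu)
  z <- backsolve(r, t(centred), transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(r))) + colSums(z * z))
}

#' Cross-validated selection of the shrinkage weight
#'
#' K-fold cross-validation over the candidate `eta_grid`: on each training
#' split the mean and the shrunken MLE covariance are fitted, and the
#' held-out fold is scored by its average per-curve Gaussian log-density.
#' The `eta` maximizing the mean held-out score wins; ties are broken toward
#' the smaller `eta` (more regularization). Candidates whose training
#' covariance fails to factorize score `-Inf`; if all candidates fail an
#' estimation-failure error is raised.
#'
#' @param curves a [curve_set()] with `n >= 2 * folds`.
#' @param config a [shrinkage_config()] (its `eta_grid`, `folds` and `seed`
#'   are used; a fixed `eta` is returned as-is).
#' @return The selected `eta` in `[0, 1]`.
#' @export
select_shrinkage_cv <- function(curves, config = shrinkage_config()) {
  assert_curve_set(curves)
  assert_shrinkage(config)
  if (is.numeric(config$eta)) {
    return(config$eta)
  }
  n <- nrow(curves$values)
  folds <- config$folds
  if (n < 2L * folds) {
    stop_insufficient_sample(sprintf(
      "cross-validation with %d folds needs at least %d curves (have %d)",
      folds, 2L * folds, n
    ))
  }
  fold_id <- with_local_seed(
    config$seed,
    sample(rep_len(seq_len(folds), n))
  )
  grid_eta <- config$eta_grid
  scores <- matrix(NA_real_, nrow = folds, ncol = length(grid_eta))
  for (k in seq_len(folds)) {
    train <- curves$values[fold_id != k, , drop = FALSE]
    test <- curves$values[fold_id == k, , drop = FALSE]
    mu <- colMeans(train)
    centred <- sweep(train, 2L, mu)
    sigma <- crossprod(centred) / nrow(train)
    if (any(diag(sigma) <= 0)) {
      scores[k, ] <- -Inf
      next
    }
    for (j in seq_along(grid_eta)) {
      sh <- shrink_covariance(sigma, grid_eta[j])
      scores[k, j] <- mean(gaussian_logdensity(test, mu, sh))
    }
  }
  mean_score <- colMeans(scores)
  if (all(!is.finite(mean_score))) {
    stop_estimation_failure("no shrinkage candidate produced a positive definite training covariance")
  }
  best <- max(mean_score[is.finite(mean_score)])
  # ties (exact or within float noise) resolve to the smallest eta
  grid_eta[which(mean_score >= best - 1e-12 * max(1, abs(best)))[1L]]
}

# Resolve a shrinkage config against data: fixed eta passes through, "cv"
# triggers selection. Used by the selection / inference / classification
# pipelines so eta is chosen once per group on the full grid.
resolve_eta <- function(curves, config) {
  assert_shrinkage(config)
  if (is.numeric(config$eta)) config$eta else select_shrinkage_cv(curves, config)
}

# MLE parameters with the covariance shrunk by eta.
estimate_shrunk_params <- function(curves, eta) {
  params <- estimate_gaussian_params(curves)
  gaussian_grid_params(
    params$grid, params$mean,
    shrink_covariance(params$cov, eta)
  )
}

#' Project irregularly sampled curves onto a common grid
#'
#' Each raw curve (its own observation times and values) is independently
#' smoothed with a Gaussian-kernel local-constant (Nadaraya-Watson)
#' estimator and evaluated on the target grid. `bandwidth = "auto"` applies
#' Silverman's rule of thumb to each curve's observation times. Boundary
#' bias of the local-constant smoother is accepted and documented; curve
#' registration/alignment is deliberately *not* performed here.
#'
#' @param raw_curves list of curves, each a list (or data.frame) with
#'   components `times` and `values` of equal length `>= 2`.
#' @param target a [grid_domain()]; curves are evaluated on `target$points`.
#' @param bandwidth positive kernel bandwidth in time units, or `"auto"`.
#' @param label optional group label for the returned [curve_set()].
#' @return A [curve_set()] on the target grid.
#' @export
smooth_to_common_grid <- function(raw_curves, target, bandwidth = "auto",
                                  label = NULL) {
  assert_grid(target)
  if (!is.list(raw_curves) || length(raw_curves) == 0L) {
    stop_invalid_input("'raw_curves' must be a nonempty list of (times, values) pairs")
  }
  if (is.numeric(bandwidth) && (length(bandwidth) != 1L || bandwidth <= 0)) {
    stop_invalid_parameter("'bandwidth' must be a positive scalar or \"auto\"")
  }
  out <- matrix(NA_real_, nrow = length(raw_curves), ncol = target$p)
  for (i in seq_along(raw_curves)) {
    crv <- raw_curves[[i]]
    times <- as.numeric(crv$times)
    values <- as.numeric(crv$values)
    keep <- times >= target$t_min & times <= target$t_max
    times <- times[keep]
    values <- values[keep]
    if (length(times) < 2L) {
      stop_invalid_input(sprintf(
        "curve %d has fewer than 2 observations inside the target domain", i
      ))
    }
    h <- if (identical(bandwidth, "auto")) {
      max(stats::bw.nrd0(times), 1e-8 * grid_lambda(target))
    } else {
      bandwidth
    }
    # Nadaraya-Watson with Gaussian kernel, evaluated at every target point.
    w <- stats::dnorm(outer(target$points, times, "-") / h)
    sw <- rowSums(w)
    # where all weights underflow (tiny bandwidth far from data), fall back
    # to the nearest observation
    tiny <- sw <= .Machine$double.xmin
    est <- as.numeric((w %*% values)) / sw
    if (any(tiny)) {
      nearest <- vapply(
        target$points[tiny],
        function(t0) values[which.min(abs(times - t0))],
        0
      )
      est[tiny] <- nearest
    }
    out[i, ] <- est
  }
  curve_set(out, target, label = label)
}
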