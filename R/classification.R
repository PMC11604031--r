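#' Fit a quadratic discriminant on (a restriction of) the grid
#'
#' Estimates per-group Gaussian parameters (with per-group shrinkage),
#' restricts them to the given grid indices, and stores the pieces of the
#' Gaussian log-likelihood-ratio discriminant. `"empirical"` priors are the
#' training proportions `n/(n+m)` and `m/(n+m)`.
#'
#' @param train_x,train_y training [curve_set()]s on a common grid.
#' @param indices grid indices defining the restriction (default: full grid).
#' @param shrinkage a [shrinkage_config()]; `eta` is resolved per group on
#'   the full grid before restriction.
#' @param priors `"empirical"` or a single numeric prior for group X in
#'   `(0, 1)` (group Y gets the complement).
#' @return An object of class `kld_discriminant`.
#' @export
fit_discriminant <- function(train_x, train_y, indices = NULL,
                             shrinkage = shrinkage_config(),
                             priors = "empirical") {
  assert_curve_set(train_x)
  assert_curve_set(train_y)
  if (!same_grid(train_x$grid, train_y$grid)) {
    stop_invalid_input("both training sets must be observed on the same grid")
  }
  p <- train_x$grid$p
  if (is.null(indices)) indices <- seq_len(p)
  indices <- check_indices(indices, p)
  n <- nrow(train_x$values)
  m <- nrow(train_y$values)
  if (identical(priors, "empirical")) {
    prior_x <- n / (n + m)
  } else if (is.numeric(priors) && length(priors) == 1L &&
    priors > 0 && priors < 1) {
    prior_x <- priors
  } else {
    stop_invalid_parameter("'priors' must be \"empirical\" or a single value in (0, 1)")
  }
  eta_x <- resolve_eta(train_x, shrinkage)
  eta_y <- resolve_eta(train_y, shrinkage)
  params_x <- restrict_params(estimate_shrunk_params(train_x, eta_x), indices)
  params_y <- restrict_params(estimate_shrunk_params(train_y, eta_y), indices)
  rx <- chol_or_stop(params_x$cov, "cov_x")
  ry <- chol_or_stop(params_y$cov, "cov_y")
  structure(
    list(
      params_x = params_x, params_y = params_y,
      prior_x = prior_x, prior_y = 1 - prior_x,
      indices = indices, eta = c(x = eta_x, y = eta_y),
      chol_x = rx, chol_y = ry,
      logdet_x = 2 * sum(log(diag(rx))),
      logdet_y = 2 * sum(log(diag(ry)))
    ),
    class = "kld_discriminant"
  )
}

#' @export
print.kld_discriminant <- function(x, ...) {
  cat(sprintf(
    "<kld_discriminant> %d grid points [%d..%d], priors (%.3f, %.3f)\n",
    length(x$indices), min(x$indices), max(x$indices), x$prior_x, x$prior_y
  ))
  invisible(x)
}

#' Quadratic discriminant score of one or more curves
#'
#' The Gaussian log-likelihood ratio with priors,
#' `D(z) = ln[pi_X f_X(z)] - ln[pi_Y f_Y(z)]`, evaluated on the fitted
#' restriction:
#' `D(z) = (1/2)(z - mu_Y)' S_Y^-1 (z - mu_Y) - (1/2)(z - mu_X)' S_X^-1 (z - mu_X)
#'  - (1/2) ln(det S_X / det S_Y) + ln(pi_X / pi_Y)`.
#' Positive sign classifies `z` into group X. Curves are passed on the full
#' grid; the restriction to the fitted indices is applied internally, so
#' grid columns outside the fitted window never influence the score.
#'
#' @param z numeric vector of length `p` (full grid) or of
#'   `length(indices)`, or a matrix with curves in rows.
#' @param params a fitted `kld_discriminant`.
#' @return Numeric score(s), one per curve.
#' @export
discriminant_score <- function(z, params) {
  if (!inherits(params, "kld_discriminant")) {
    stop_invalid_input("expected a 'kld_discriminant' object")
  }
  zmat <- if (is.matrix(z)) z else matrix(z, nrow = 1L)
  k <- length(params$indices)
  full_p <- max(params$indices)
  if (ncol(zmat) == k) {
    # already restricted
  } else if (ncol(zmat) >= full_p) {
    zmat <- zmat[, params$indices, drop = FALSE]
  } else {
    stop_invalid_input(sprintf(
      "curve length %d matches neither the full grid nor the %d fitted indices",
      ncol(zmat), k
    ))
  }
  qx <- quad_forms(zmat, params$params_x$mean, params$chol_x)
  qy <- quad_forms(zmat, params$params_y$mean, params$chol_y)
  0.5 * qy - 0.5 * qx - 0.5 * (params$logdet_x - params$logdet_y) +
    log(params$prior_x / params$prior_y)
}

# (z - mu)' S^-1 (z - mu) for each row of z, via the stored factor.
quad_forms <- function(zmat, mu, r) {
  centred <- sweep(zmat, 2L, mu)
  v <- backsolve(r, t(centred), transpose = TRUE)
  colSums(v * v)
}

#' Misclassification error of the domain-restricted discriminant
#'
#' Replicated train/test evaluation of the full pipeline at a given length
#' fraction: per replicate, a stratified random split (fraction `split` of
#' each group to training); on the training half the interval of maximum
#' divergence is selected and the discriminant fitted on its indices
#' (shrinkage resolved on the training half); the held-out half is
#' classified by the sign of the discriminant score and the misclassified
#' fraction recorded. At `c = 1` the pipeline reduces to full-domain
#' quadratic discriminant analysis.
#'
#' @inheritParams select_interval
#' @param split training fraction in `(0, 1)` (default 0.5).
#' @param B number of split replicates.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param alpha miscoverage for the reported error quantiles.
#' @param priors passed to [fit_discriminant()].
#' @return A list with `c`, `w`, `err_mean`, `err_lo`, `err_hi` and the
#'   per-replicate `errors` vector.
#' @export
estimate_error <- function(curves_x, curves_y, c, split = 0.5, B = 100L,
                           seed = NULL, shrinkage = shrinkage_config(),
                           alpha = 0.05, priors = "empirical") {
  assert_curve_set(curves_x)
  assert_curve_set(curves_y)
  if (!same_grid(curves_x$grid, curves_y$grid)) {
    stop_invalid_input("both curve sets must be observed on the same grid")
  }
  if (length(split) != 1L || !is.finite(split) || split <= 0 || split >= 1) {
    stop_invalid_parameter("'split' must lie in (0, 1)")
  }
  n <- nrow(curves_x$values)
  m <- nrow(curves_y$values)
  n_tr <- round(split * n)
  m_tr <- round(split * m)
  if (min(n_tr, n - n_tr, m_tr, m - m_tr) < 2L) {
    stop_invalid_parameter("each split side needs at least 2 curves per group")
  }
  grid <- curves_x$grid
  seeds <- derive_seeds(seed, B)
  errors <- vapply(seq_len(B), function(b) {
    with_local_seed(seeds[b], {
      ix <- sample.int(n, n_tr)
      iy <- sample.int(m, m_tr)
    })
    tr_x <- curve_set(curves_x$values[ix, , drop = FALSE], grid, curves_x$label)
    tr_y <- curve_set(curves_y$values[iy, , drop = FALSE], grid, curves_y$label)
    te_x <- curves_x$values[-ix, , drop = FALSE]
    te_y <- curves_y$values[-iy, , drop = FALSE]
    sel <- select_interval(tr_x, tr_y, c, shrinkage = shrinkage)
    idx <- sel$window$start:sel$window$end
    fit <- fit_discriminant(tr_x, tr_y, idx,
      shrinkage = shrinkage, priors = priors
    )
    sx <- discriminant_score(te_x, fit)
    sy <- discriminant_score(te_y, fit)
    (sum(sx <= 0) + sum(sy > 0)) / (length(sx) + length(sy))
  }, 0)
  qs <- stats::quantile(errors, probs = c(alpha / 2, 1 - alpha / 2),
    names = FALSE, type = 7
  )
  list(
    c = c,
    w = window_size_from_fraction(c, grid$p),
    err_mean = mean(errors),
    err_lo = qs[1],
    err_hi = qs[2],
    errors = errors
  )
}

#' Misclassification error across a ladder of length fractions
#'
#' Runs [estimate_error()] for every `c` in `c_grid` and stacks the summary
#' rows; the companion of the selector's elbow plot on the classification
#' side.
#'
#' @inheritParams estimate_error
#' @param c_grid vector of length fractions in `(0, 1]`.
#' @return A data.frame with columns `c`, `w`, `err_mean`, `err_lo`, `err_hi`.
#' @export
error_vs_length <- function(curves_x, curves_y, c_grid, split = 0.5, B = 100L,
                            seed = NULL, shrinkage = shrinkage_config(),
                            alpha = 0.05, priors = "empirical") {
  seeds <- derive_seeds(seed, length(c_grid))
  rows <- lapply(seq_along(c_grid), function(i) {
    res <- estimate_error(curves_x, curves_y, c_grid[i],
      split = split, B = B,
      seed = seeds[i], shrinkage = shrinkage, alpha = alpha, priors = priors
    )
    data.frame(
      c = res$c, w = res$w, err_mean = res$err_mean,
      err_lo = res$err_lo, err_hi = res$err_hi
    )
  })
  do.call(rbind, rows)
}
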