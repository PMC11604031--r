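#' Bootstrap distribution of the selected interval's center
#'
#' Nonparametric bootstrap for the interval of local maximum divergence:
#' each replicate resamples `n` curves with replacement from group X and `m`
#' from group Y (independently within group, exactly at the original sizes),
#' reruns the interval selection, and records the selected window's center
#' in time units. The shrinkage weight `eta` is resolved once on the full
#' data and held fixed across replicates.
#'
#' @inheritParams select_interval
#' @param B number of bootstrap replicates (`>= 1`).
#' @param seed integer seed driving the resampling.
#' @return Numeric vector of `B` center times.
#' @export
bootstrap_interval_centers <- function(curves_x, curves_y, c, B = 1000L,
                                       seed = NULL,
                                       shrinkage = shrinkage_config(),
                                       symmetrized = FALSE) {
  assert_curve_set(curves_x)
  assert_curve_set(curves_y)
  if (!same_grid(curves_x$grid, curves_y$grid)) {
    stop_invalid_input("both curve sets must be observed on the same grid")
  }
  if (length(B) != 1L || !is.finite(B) || B < 1 || B != round(B)) {
    stop_invalid_parameter("'B' must be a positive integer")
  }
  eta_x <- resolve_eta(curves_x, shrinkage)
  eta_y <- resolve_eta(curves_y, shrinkage)
  n <- nrow(curves_x$values)
  m <- nrow(curves_y$values)
  grid <- curves_x$grid
  with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      ix <- sample.int(n, n, replace = TRUE)
      iy <- sample.int(m, m, replace = TRUE)
      bx <- curve_set(curves_x$values[ix, , drop = FALSE], grid, curves_x$label)
      by <- curve_set(curves_y$values[iy, , drop = FALSE], grid, curves_y$label)
      res <- tryCatch(
        select_from_params(
          estimate_shrunk_params(bx, eta_x),
          estimate_shrunk_params(by, eta_y),
          c,
          symmetrized = symmetrized
        ),
        kld_error = function(e) {
          stop_estimation_failure(sprintf(
            "bootstrap replicate %d failed: %s", b, conditionMessage(e)
          ))
        }
      )
      res$window$center_time
    }, 0)
  })
}

#' Percentile confidence interval for the interval center
#'
#' Empirical `alpha/2` and `1 - alpha/2` quantiles of the bootstrap centers
#' (percentile bootstrap, linear-interpolation quantile convention).
#'
#' @param centers numeric vector of bootstrap center times.
#' @param alpha miscoverage level in `(0, 1)`; default `0.05` for a 95\%
#'   interval.
#' @return Numeric vector `c(lo, hi)`.
#' @export
center_confidence_interval <- function(centers, alpha = 0.05) {
  if (length(centers) == 0L || anyNA(centers)) {
    stop_invalid_input("'centers' must be a nonempty numeric vector without NAs")
  }
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid_parameter("'alpha' must lie in (0, 1)")
  }
  q <- stats::quantile(centers, probs = c(alpha / 2, 1 - alpha / 2),
    names = FALSE, type = 7
  )
  c(lo = q[1], hi = q[2])
}

#' Confidence set for the selected interval
#'
#' The union of the balls `B(t, r)` over all centers `t` in the confidence
#' interval, which for an interval of centers is exactly
#' `[lo - r, hi + r]`, optionally clipped to the grid domain.
#'
#' @param ci numeric `c(lo, hi)` with `lo <= hi`.
#' @param radius_time nonnegative half-width of the selected window in time
#'   units.
#' @param grid optional [grid_domain()]; when supplied the set is clipped to
#'   `[t_min, t_max]`.
#' @return Numeric vector `c(lo, hi)`.
#' @export
confidence_set <- function(ci, radius_time, grid = NULL) {
  if (length(ci) != 2L || anyNA(ci) || ci[1] > ci[2]) {
    stop_invalid_input("'ci' must be c(lo, hi) with lo <= hi")
  }
  if (length(radius_time) != 1L || !is.finite(radius_time) || radius_time < 0) {
    stop_invalid_parameter("'radius_time' must be nonnegative")
  }
  out <- c(lo = ci[[1]] - radius_time, hi = ci[[2]] + radius_time)
  if (!is.null(grid)) {
    assert_grid(grid)
    out[1] <- max(out[1], grid$t_min)
    out[2] <- min(out[2], grid$t_max)
  }
  out
}

#' Full bootstrap uncertainty quantification for a selected interval
#'
#' Convenience wrapper: runs [select_interval()] on the full data, then
#' [bootstrap_interval_centers()], [center_confidence_interval()] and
#' [confidence_set()], returning everything in one object.
#'
#' @inheritParams bootstrap_interval_centers
#' @param alpha miscoverage level (default `0.05`).
#' @return An object of class `kld_bootstrap` with fields `selection`,
#'   `centers`, `B`, `alpha`, `c`, `radius_time`, `ci`, `confidence_set`.
#' @export
kld_bootstrap <- function(curves_x, curves_y, c, B = 1000L, alpha = 0.05,
                          seed = NULL, shrinkage = shrinkage_config(),
                          symmetrized = FALSE) {
  sel <- select_interval(curves_x, curves_y, c,
    shrinkage = shrinkage, symmetrized = symmetrized
  )
  centers <- bootstrap_interval_centers(curves_x, curves_y, c,
    B = B, seed = seed, shrinkage = shrinkage, symmetrized = symmetrized
  )
  ci <- center_confidence_interval(centers, alpha)
  cs <- confidence_set(ci, sel$window$radius_time, grid = curves_x$grid)
  structure(
    list(
      selection = sel, centers = centers, B = as.integer(B), alpha = alpha,
      c = c, radius_time = sel$window$radius_time,
      ci = ci, confidence_set = cs
    ),
    class = "kld_bootstrap"
  )
}

#' @export
print.kld_bootstrap <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<kld_bootstrap> B = %d, alpha = %g, c = %g\n",
      "  center median %.4g, CI [%.4g, %.4g], confidence set [%.4g, %.4g]\n"
    ),
    x$B, x$alpha, x$c, stats::median(x$centers),
    x$ci[1], x$ci[2], x$confidence_set[1], x$confidence_set[2]
  ))
  invisible(x)
}

#' Serialize a bootstrap result to JSON (and optionally the centers to CSV)
#'
#' @param result a `kld_bootstrap` object.
#' @param path JSON output path.
#' @param centers_csv optional path for a one-column CSV dump of the raw
#'   bootstrap centers (for density plotting).
#' @return `path`, invisibly.
#' @export
write_bootstrap_json <- function(result, path, centers_csv = NULL) {
  if (!inherits(result, "kld_bootstrap")) {
    stop_invalid_input("expected a 'kld_bootstrap' object")
  }
  qs <- stats::quantile(result$centers,
    probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE, type = 7
  )
  payload <- list(
    B = result$B, alpha = result$alpha, c = result$c,
    centers_summary = list(
      median = stats::median(result$centers),
      quantiles = list(
        q05 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q95 = qs[5]
      )
    ),
    ci = list(lo = result$ci[[1]], hi = result$ci[[2]]),
    confidence_set = list(
      lo = result$confidence_set[[1]], hi = result$confidence_set[[2]]
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(centers_csv)) {
    utils::write.csv(
      data.frame(center_time = result$centers),
      centers_csv,
      row.names = FALSE
    )
  }
  invisible(path)
}
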