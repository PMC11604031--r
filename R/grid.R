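#' Discrete grid over a compact domain
#'
#' The index set on which curves are observed: `p` strictly increasing time
#' points inside `[t_min, t_max]`. The canonical design used throughout the
#' package (and by the simulation scenarios) is the left-closed equally spaced
#' grid `t_k = t_min + (k-1) * (t_max - t_min) / p`, `k = 1..p`, i.e. the
#' right endpoint is excluded.
#'
#' @param p number of grid points (positive integer).
#' @param t_min,t_max domain endpoints, `t_max > t_min`.
#' @param points optional explicit vector of `p` strictly increasing times;
#'   when supplied it overrides the equally spaced construction (but must lie
#'   inside `[t_min, t_max]`).
#' @return An object of class `grid_domain` with fields `t_min`, `t_max`,
#'   `p` and `points`.
#' @examples
#' g <- grid_domain(100, 0, pi)
#' head(g$points)
#' @export
grid_domain <- function(p, t_min = 0, t_max = pi, points = NULL) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != round(p)) {
    stop_invalid_parameter("'p' must be a positive integer")
  }
  p <- as.integer(p)
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min) {
    stop_invalid_parameter("'t_max' must exceed 't_min'")
  }
  if (is.null(points)) {
    points <- t_min + (seq_len(p) - 1) * (t_max - t_min) / p
  } else {
    if (length(points) != p) {
      stop_invalid_parameter("'points' must have length 'p'")
    }
    if (any(diff(points) <= 0)) {
      stop_invalid_parameter("'points' must be strictly increasing")
    }
    if (points[1] < t_min || points[p] > t_max) {
      stop_invalid_parameter("'points' must lie inside [t_min, t_max]")
    }
  }
  structure(
    list(t_min = t_min, t_max = t_max, p = p, points = as.numeric(points)),
    class = "grid_domain"
  )
}

#' @export
print.grid_domain <- function(x, ...) {
  cat(sprintf(
    "<grid_domain> p = %d points on [%g, %g] (lambda = %g)\n",
    x$p, x$t_min, x$t_max, grid_lambda(x)
  ))
  invisible(x)
}

# Lebesgue measure of the domain.
grid_lambda <- function(grid) grid$t_max - grid$t_min

assert_grid <- function(grid) {
  if (!inherits(grid, "grid_domain")) {
    stop_invalid_input("expected a 'grid_domain' object")
  }
  invisible(grid)
}

same_grid <- function(a, b, tol = 1e-10) {
  a$p == b$p && isTRUE(all.equal(a$points, b$points, tolerance = tol))
}
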