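# Shared fixture builders. Everything is generated in code; no data files.

# Random symmetric positive-definite matrix with eigenvalues bounded away
# from zero.
rand_pd <- function(p, jitter = 0.5) {
  a <- matrix(rnorm(p * p), p, p)
  crossprod(a) / p + jitter * diag(p)
}

# Gaussian grid parameters with random mean and PD covariance on a
# canonical [0, pi) grid.
rand_params <- function(p, grid = grid_domain(p, 0, pi)) {
  gaussian_grid_params(grid, rnorm(p), rand_pd(p))
}

# Two curve sets of iid N(0,1) noise with an optional mean shift added to a
# block of columns of the first group.
shifted_noise_groups <- function(n, p, shift_cols = integer(0), shift = 0) {
  grid <- grid_domain(p, 0, pi)
  x <- matrix(rnorm(n * p), n, p)
  if (length(shift_cols) > 0) {
    x[, shift_cols] <- x[, shift_cols] + shift
  }
  y <- matrix(rnorm(n * p), n, p)
  list(
    x = curve_set(x, grid, label = "X"),
    y = curve_set(y, grid, label = "Y")
  )
}

# Independent KL oracle: direct evaluation of the Gaussian divergence with
# solve() and determinant(), no Cholesky, no shared code with the package.
kl_oracle <- function(mx, Sx, my, Sy) {
  p <- length(mx)
  iSy <- solve(Sy)
  d <- my - mx
  0.5 * (sum(diag(iSy %*% Sx)) - p + drop(t(d) %*% iSy %*% d) +
    determinant(Sy, logarithm = TRUE)$modulus -
    determinant(Sx, logarithm = TRUE)$modulus)
}

# Independent Gaussian log-density (solve/determinant path).
logdens_oracle <- function(z, mu, S) {
  p <- length(mu)
  d <- z - mu
  -0.5 * (p * log(2 * pi) +
    as.numeric(determinant(S, logarithm = TRUE)$modulus) +
    drop(t(d) %*% solve(S) %*% d))
}
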