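test_that("univariate KL matches the closed form and a quadrature oracle", {
  expect_equal(kl_gaussian_univariate(0, 1, 0, 1), 0)
  expect_equal(kl_gaussian_univariate(0, 1, 1, 1), 0.5)
  # frozen from the quadrature oracle below: (1 - ln 2)/2
  expect_equal(kl_gaussian_univariate(0, 2, 0, 1), 0.5 * (1 - log(2)),
    tolerance = 1e-12
  )

  quad_kl <- function(mx, vx, my, vy) {
    integrand <- function(t) {
      fx <- dnorm(t, mx, sqrt(vx))
      fx * (dnorm(t, mx, sqrt(vx), log = TRUE) -
        dnorm(t, my, sqrt(vy), log = TRUE))
    }
    integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value
  }
  cases <- list(c(0, 2, 0, 1), c(1, 0.5, -1, 3), c(2, 4, 2, 0.25))
  for (cs in cases) {
    expect_equal(
      kl_gaussian_univariate(cs[1], cs[2], cs[3], cs[4]),
      quad_kl(cs[1], cs[2], cs[3], cs[4]),
      tolerance = 1e-7
    )
  }

  expect_error(kl_gaussian_univariate(0, 0, 0, 1), class = "kld_invalid_parameter")
  expect_error(kl_gaussian_univariate(0, 1, 0, -2), class = "kld_invalid_parameter")
})

test_that("multivariate KL: identity, diagonal factorization, Monte Carlo oracle", {
  set.seed(101)
  p <- 4
  grid <- grid_domain(p, 0, pi)
  px <- rand_params(p, grid)
  expect_equal(kl_gaussian_multivariate(px, px), 0)

  # diagonal covariances: KL factorizes into a sum of univariate terms
  dx <- gaussian_grid_params(grid, c(0, 1, -1, 2), diag(c(1, 2, 0.5, 3)))
  dy <- gaussian_grid_params(grid, c(1, 1, 0, -1), diag(c(2, 1, 1, 1.5)))
  expected <- sum(vapply(1:p, function(i) {
    kl_gaussian_univariate(dx$mean[i], dx$cov[i, i], dy$mean[i], dy$cov[i, i])
  }, 0))
  expect_equal(kl_gaussian_multivariate(dx, dy), expected, tolerance = 1e-12)

  # Monte Carlo oracle: KL = E_X[ln f_X - ln f_Y]
  skip_if_not_installed("MASS")
  set.seed(7)
  g3 <- grid_domain(3, 0, pi)
  px <- rand_params(3, g3)
  py <- rand_params(3, g3)
  n_mc <- 2e5
  draws <- MASS::mvrnorm(n_mc, px$mean, px$cov)
  lr <- vapply(seq_len(n_mc), function(i) {
    logdens_oracle(draws[i, ], px$mean, px$cov) -
      logdens_oracle(draws[i, ], py$mean, py$cov)
  }, 0)
  se <- sd(lr) / sqrt(n_mc)
  expect_lt(
    abs(kl_gaussian_multivariate(px, py) - mean(lr)),
    3 * se
  )
})

test_that("multivariate KL input validation and stabilization", {
  px <- rand_params(3)
  py <- rand_params(4)
  expect_error(kl_gaussian_multivariate(px, py), class = "kld_invalid_parameter")

  grid <- grid_domain(3, 0, pi)
  singular <- gaussian_grid_params(grid, rep(0, 3), matrix(1, 3, 3))
  ok <- rand_params(3, grid)
  err <- tryCatch(
    kl_gaussian_multivariate(ok, singular),
    error = function(e) e
  )
  expect_s3_class(err, "kld_not_positive_definite")
  expect_match(conditionMessage(err), "cov_y")
  # jitter stabilization turns the failure into a finite value
  expect_gte(kl_gaussian_multivariate(ok, singular, stabilize = TRUE), 0)
})

test_that("local KL restricts correctly and delegates singletons", {
  set.seed(42)
  p <- 6
  grid <- grid_domain(p, 0, pi)
  px <- rand_params(p, grid)
  py <- rand_params(p, grid)

  expect_equal(
    kl_local(px, py, 1:p),
    kl_gaussian_multivariate(px, py)
  )

  # restriction agrees with building the restricted parameters by hand
  idx <- c(2, 4, 5)
  sub <- function(par) {
    gaussian_grid_params(
      grid_domain(3, 0, pi, points = grid$points[idx]),
      par$mean[idx], par$cov[idx, idx]
    )
  }
  expect_equal(kl_local(px, py, idx), kl_gaussian_multivariate(sub(px), sub(py)))

  # equal restrictions on A but different elsewhere -> 0 on A
  mean_y <- px$mean
  mean_y[6] <- mean_y[6] + 5
  cov_y <- px$cov
  cov_y[6, 6] <- cov_y[6, 6] + 2
  py_eq <- gaussian_grid_params(grid, mean_y, cov_y)
  expect_equal(kl_local(px, py_eq, 1:4), 0)

  # singleton = univariate formula
  expect_equal(
    kl_local(px, py, 3),
    kl_gaussian_univariate(px$mean[3], px$cov[3, 3], py$mean[3], py$cov[3, 3])
  )

  expect_error(kl_local(px, py, integer(0)), class = "kld_invalid_parameter")
  expect_error(kl_local(px, py, c(1, 99)), class = "kld_invalid_parameter")
  expect_error(kl_local(px, py, c(2, 2)), class = "kld_invalid_parameter")
})

test_that("KL nonnegativity and zero-iff-equal over random parameter pairs", {
  set.seed(11)
  for (i in 1:1000) {
    p <- sample(2:6, 1)
    grid <- grid_domain(p, 0, pi)
    px <- rand_params(p, grid)
    py <- rand_params(p, grid)
    idx <- sort(sample(p, sample(p, 1)))
    expect_gte(kl_local(px, py, idx), 0)
  }
  # zero exactly iff restricted parameters agree
  set.seed(12)
  for (i in 1:25) {
    p <- 5
    grid <- grid_domain(p, 0, pi)
    px <- rand_params(p, grid)
    expect_lt(kl_local(px, px, 1:3), 1e-10)
    py <- gaussian_grid_params(grid, px$mean + c(0, 0, 0, 0, 1e-3), px$cov)
    expect_lt(kl_local(px, py, 1:4), 1e-10) # perturbed outside A
    pz <- gaussian_grid_params(grid, px$mean + c(1e-2, 0, 0, 0, 0), px$cov)
    expect_gt(kl_local(px, pz, 1:4), 1e-10) # perturbed inside A
  }
})

test_that("local KL is monotone under nested index sets", {
  set.seed(13)
  for (i in 1:50) {
    p <- sample(3:12, 1)
    grid <- grid_domain(p, 0, pi)
    px <- rand_params(p, grid)
    py <- rand_params(p, grid)
    a <- sort(sample(p, sample(2:p, 1)))
    a_sub <- sort(sample(a, sample(seq_len(length(a) - 1), 1)))
    expect_lte(kl_local(px, py, a_sub), kl_local(px, py, a) + 1e-10)
  }
  # fixed 5-point nested example, checked against the independent oracle
  set.seed(14)
  grid <- grid_domain(5, 0, pi)
  px <- rand_params(5, grid)
  py <- rand_params(5, grid)
  a <- 1:4
  a_sub <- 2:3
  kl_a <- kl_oracle(px$mean[a], px$cov[a, a], py$mean[a], py$cov[a, a])
  kl_s <- kl_oracle(px$mean[a_sub], px$cov[a_sub, a_sub], py$mean[a_sub], py$cov[a_sub, a_sub])
  expect_lte(kl_s, kl_a)
  expect_equal(kl_local(px, py, a), as.numeric(kl_a), tolerance = 1e-10)
  expect_equal(kl_local(px, py, a_sub), as.numeric(kl_s), tolerance = 1e-10)
})

test_that("equal covariances reduce 2*KL to the squared Mahalanobis distance", {
  set.seed(15)
  for (i in 1:20) {
    p <- sample(2:8, 1)
    grid <- grid_domain(p, 0, pi)
    S <- rand_pd(p)
    px <- gaussian_grid_params(grid, rnorm(p), S)
    py <- gaussian_grid_params(grid, rnorm(p), S)
    idx <- sort(sample(p, sample(2:p, 1)))
    d <- py$mean[idx] - px$mean[idx]
    maha <- drop(t(d) %*% solve(S[idx, idx]) %*% d)
    expect_equal(2 * kl_local(px, py, idx), maha, tolerance = 1e-8)
  }
})

test_that("symmetrized divergence is symmetric and averages both directions", {
  set.seed(16)
  px <- rand_params(5)
  py <- rand_params(5, px$grid)
  expect_equal(kl_symmetrized(px, px, 1:5), 0)
  expect_equal(
    kl_symmetrized(px, py, 2:4),
    kl_symmetrized(py, px, 2:4)
  )
  # univariate case (1,2) vs (0,1): direct double evaluation of the
  # closed form
  grid1 <- grid_domain(1, 0, pi)
  a <- gaussian_grid_params(grid1, 1, matrix(2))
  b <- gaussian_grid_params(grid1, 0, matrix(1))
  fwd <- 0.5 * (2 / 1 - 1 + (1 - 0)^2 / 1 + log(1 / 2))
  bwd <- 0.5 * (1 / 2 - 1 + (0 - 1)^2 / 2 + log(2 / 1))
  expect_equal(kl_symmetrized(a, b, 1), (fwd + bwd) / 2, tolerance = 1e-12)
})
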