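test_that("vertex quadrature integrates linear fields exactly on triangles", {
  # the lumped load m_i f_i sums to int f for linear f
  mesh <- generate_mesh(domain_spec(0.5, 1), 0.25)
  g <- fem_geom(mesh$X, mesh$tri)
  m <- mass_lumped(g, mesh$tri, nrow(mesh$X))
  for (f in list(function(y, z) 1 + 0 * y,
                 function(y, z) 2 * y - 3 * z + 1)) {
    vals <- f(mesh$X[, 1], mesh$X[, 2])
    # exact integral over the unit-area rectangle [-0.5,0.5] x [-1,0]:
    # a linear field integrates to its centroid value times the area
    exact <- f(0, -0.5) * 1
    expect_equal(sum(m * vals), exact, tolerance = 1e-12)
  }
})

test_that("two-point Gauss edge rule is exact through cubics", {
  q <- edge_gauss2()
  L <- 2.7
  for (k in 0:3) {
    approx <- sum(q$w * (q$t * L)^k) * L
    exact <- L^(k + 1) / (k + 1)
    expect_equal(approx, exact, tolerance = 1e-12, label = paste("degree", k))
  }
  # degree 4 must NOT be exact (the rule is order 2 Gaussian)
  expect_gt(abs(sum(q$w * q$t^4) - 1 / 5), 1e-4)
})

test_that("gradient recovery is exact for linear fields and consistent for constants", {
  mesh <- generate_mesh(domain_spec(0.5, 1), 0.2)
  z_lin <- 3 * mesh$X[, 1] - 2 * mesh$X[, 2] + 0.5
  g <- recover_gradient(mesh, z_lin, current = FALSE)
  expect_equal(g[, 1], rep(3, nrow(mesh$X)), tolerance = 1e-10)
  expect_equal(g[, 2], rep(-2, nrow(mesh$X)), tolerance = 1e-10)
  g0 <- recover_gradient(mesh, rep(4.2, nrow(mesh$X)), current = FALSE)
  expect_equal(max(abs(g0)), 0, tolerance = 1e-12)
})

test_that("recovered gradients converge for a smooth quadratic field", {
  err <- vapply(c(0.2, 0.1), function(h) {
    mesh <- generate_mesh(domain_spec(0.5, 1), h)
    y <- mesh$X[, 1]; z <- mesh$X[, 2]
    g <- recover_gradient(mesh, y^2 + y * z - z^2, current = FALSE)
    interior <- abs(y) < 0.4 & z > -0.9 & z < -0.1
    max(abs(g[interior, 1] - (2 * y + z)[interior]),
        abs(g[interior, 2] - (y - 2 * z)[interior]))
  }, 0)
  expect_lt(err[2], 0.7 * err[1])   # at least first-order decay
})

test_that("discrete upwinding yields a non-negative off-diagonal operator", {
  mesh <- generate_mesh(domain_spec(0.5, 1), 0.25)
  n <- nrow(mesh$X)
  g <- fem_geom(mesh$X, mesh$tri)
  gc <- cbind(rep(1, n), rep(-2, n))
  K <- -stiffness_weighted(g, mesh$tri, rep(1e-3, nrow(mesh$tri)), n) +
    chemotaxis_matrix(g, mesh$tri, gc, 2e-3, n)
  D <- artificial_diffusion(K)
  L <- as.matrix(K + D)
  off <- L - diag(diag(L))
  expect_true(all(off >= -1e-14))
  expect_equal(max(abs(rowSums(as.matrix(D)))), 0, tolerance = 1e-12)
  expect_equal(as.matrix(D), t(as.matrix(D)), tolerance = 1e-12)
})

test_that("FCT limiter matches an independent Zalesak implementation", {
  # 1D five-node advection-style fixture with hand-built antisymmetric fluxes
  m <- c(0.5, 1, 1, 1, 0.5)
  z_old <- c(1, 1, 0, 0, 0)
  z_low <- c(0.9, 0.7, 0.35, 0.05, 0)
  dt <- 0.4
  Fd <- matrix(0, 5, 5)
  Fd[1, 2] <- 0.3; Fd[2, 3] <- -0.9; Fd[3, 4] <- 0.8; Fd[4, 5] <- 0.12
  Fd <- Fd - t(Fd)
  Fs <- methods::as(Fd, "sparseMatrix")
  got <- fct_limit(z_low, z_old, Fs, m, dt)
  ref <- reference_limiter(z_low, z_old, Fd, m, dt)
  expect_equal(got$z, ref, tolerance = 1e-12)
  a <- as.matrix(got$alpha)
  expect_true(all(a >= 0 & a <= 1))
  # no new extrema beyond the local stencil bounds, and positivity
  expect_true(all(got$z >= 0))
  expect_lte(max(got$z), max(z_low, z_old) + 1e-12)
  # a smooth linear profile with weak fluxes is not limited
  z_lin <- seq(0.2, 1, length.out = 5)
  Fw <- Fs * 1e-4
  got2 <- fct_limit(z_lin, z_lin, Fw, m, dt)
  aw <- got2$alpha@x
  expect_true(all(aw[abs(aw) > 0] == 1))
})

test_that("limited antidiffusion respects bounds for random flux patterns", {
  set.seed(42)
  for (k in 1:15) {
    n <- 8
    m <- runif(n, 0.5, 2)
    z_old <- runif(n, 0, 2)
    z_low <- pmax(z_old + rnorm(n, 0, 0.2), 0)
    Fd <- matrix(0, n, n)
    for (i in 1:(n - 1)) Fd[i, i + 1] <- rnorm(1, 0, 0.5)
    Fd <- Fd - t(Fd)
    dt <- runif(1, 0.05, 0.5)
    got <- fct_limit(z_low, z_old, methods::as(Fd, "sparseMatrix"),
                     m, dt)
    ref <- reference_limiter(z_low, z_old, Fd, m, dt)
    expect_equal(got$z, ref, tolerance = 1e-12)
    expect_true(all(got$z >= -1e-12))
    expect_lte(max(got$z), max(z_low, z_old) + 1e-12)
    expect_gte(min(got$z), min(z_low, z_old) - 1e-12)
  }
})
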