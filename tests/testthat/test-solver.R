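pp <- scar_params()

test_that("weighted stiffness matches the hand-assembled one-triangle Laplacian", {
  coords <- rbind(c(0, 0), c(1, 0), c(0, 1))
  tri <- matrix(1:3, 1)
  g <- fem_geom(coords, tri)
  K <- as.matrix(stiffness_weighted(g, tri, 1, 3))
  # grad(phi) = (-1,-1), (1,0), (0,1) on the unit right triangle, area 1/2
  K_hand <- 0.5 * rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1))
  expect_equal(K, K_hand, tolerance = 1e-14)
  expect_equal(as.numeric(as.matrix(K) %*% rep(1, 3)), rep(0, 3),
               tolerance = 1e-14)
})

test_that("the unwounded equilibrium is a fixed point of the full step", {
  mesh <- generate_mesh(domain_spec(0.5, 0.15), 0.15)
  st <- initial_state(mesh, pp, NULL)
  res <- defect_correction_step(st, mesh, pp, dt = 1, solver_control())
  expect_true(res$accepted)
  expect_equal(res$fp_iterations, 1L)
  expect_equal(res$state$N, st$N, tolerance = 1e-12)
  expect_equal(res$state$M, st$M)
  expect_equal(res$state$c, st$c)
  expect_equal(res$state$rho, st$rho, tolerance = 1e-12)
  expect_equal(res$state$u, st$u)
  # near-zero step size reproduces the previous state (backward Euler)
  res0 <- defect_correction_step(st, mesh, pp, dt = 1e-10, solver_control())
  expect_equal(res0$state$N, st$N, tolerance = 1e-10)
})

test_that("lateral Dirichlet values hold exactly during a wound step", {
  mesh <- generate_mesh(domain_spec(), 0.12)
  st <- initial_state(mesh, pp, wound_spec())
  res <- defect_correction_step(st, mesh, pp, dt = 0.5, solver_control())
  expect_true(res$accepted)
  dir <- dirichlet_nodes(mesh)
  expect_true(all(res$state$N[dir] == pp$N_bar))
  expect_true(all(res$state$M[dir] == 0))
  expect_true(all(res$state$c[dir] == 0))
  # positivity after the accepted step
  expect_gte(min(res$state$N), 0)
  expect_gte(min(res$state$M), 0)
  expect_gte(min(res$state$c), 0)
  expect_gte(min(res$state$rho), 0)
})

test_that("an unreachable fixed-point tolerance rejects the step cleanly", {
  mesh <- generate_mesh(domain_spec(), 0.12)
  st <- initial_state(mesh, pp, wound_spec())
  ctl <- solver_control(tol_fp = 1e-300, max_fp = 2L)
  res <- defect_correction_step(st, mesh, pp, dt = 0.5, ctl)
  expect_false(res$accepted)
  expect_equal(res$reason, "fixed-point")
})

test_that("adaptive controller follows its acceptance and growth contract", {
  ctl <- solver_control(tol_lte = 1e-3, safety = 0.9, shrink_min = 0.1,
                        grow_max = 2, dt_max = 10)
  a0 <- adapt_timestep(0, 1, ctl)
  expect_true(a0$accept)
  expect_equal(a0$dt_new, 2)          # grows by grow_max
  a1 <- adapt_timestep(1e-3, 1, ctl)  # est == tol
  expect_true(a1$accept)
  expect_equal(a1$dt_new, 0.9)        # shrinks to safety * dt
  a2 <- adapt_timestep(4e-3, 1, ctl)
  expect_false(a2$accept)
  expect_equal(a2$dt_new, 0.45)       # safety * sqrt(tol/est) = 0.45
  a3 <- adapt_timestep(1e9, 1, ctl)
  expect_equal(a3$dt_new, 0.1)        # clamped at shrink_min
  expect_error(adapt_timestep(-1, 1, ctl), "estimate")
})

test_that("mechanics returns exactly zero displacement without myofibroblasts", {
  mesh <- generate_mesh(domain_spec(), 0.12)
  st <- initial_state(mesh, pp, wound_spec())
  out <- solve_mechanics(mesh, st$M, st$rho, pp)
  expect_true(out$converged)
  expect_equal(out$u, matrix(0, nrow(mesh$X), 2))
})

test_that("displacement response is linear in the traction for weak loads", {
  mesh <- generate_mesh(domain_spec(), 0.12)
  st <- initial_state(mesh, pp, wound_spec())
  Mfield <- 50 * exp(-(mesh$X[, 1] / 3)^2)   # a weak localized load
  u1 <- solve_mechanics(mesh, Mfield, st$rho, pp)
  u2 <- solve_mechanics(mesh, 2 * Mfield, st$rho, pp)
  expect_true(u1$converged && u2$converged)
  # departure from linearity is second order in the load
  dev <- max(abs(u2$u - 2 * u1$u)) / max(abs(u2$u))
  expect_lt(dev, 0.05)
  expect_gt(max(abs(u1$u)), 0)
  # mirror symmetry of the displacement under a symmetric load
  mi <- mirror_index(mesh)
  expect_equal(u1$u[mi, 1], -u1$u[, 1], tolerance = 1e-6 * max(abs(u1$u)))
  expect_equal(u1$u[mi, 2], u1$u[, 2], tolerance = 1e-6 * max(abs(u1$u)))
})

test_that("a symmetric wound stays mirror-symmetric under time stepping", {
  mesh <- generate_mesh(domain_spec(), 0.12)
  st <- initial_state(mesh, pp, wound_spec())
  out <- run_simulation(mesh, st, pp, 2)
  mi <- mirror_index(mesh)
  scl <- c(N = pp$N_bar, M = pp$N_bar, c = pp$c_w, rho = pp$rho_bar)
  for (f in c("N", "M", "c", "rho"))
    expect_lt(max(abs(out$state[[f]][mi] - out$state[[f]])) / scl[[f]],
              1e-6)
  umax <- max(abs(out$state$u))
  expect_lt(max(abs(out$state$u[mi, 1] + out$state$u[, 1])), 1e-6 * umax)
  expect_lt(max(abs(out$state$u[mi, 2] - out$state$u[, 2])), 1e-6 * umax)
  # every accepted step stayed non-negative
  expect_gte(min(out$report[, c("min_N", "min_M", "min_c", "min_rho")]), 0)
})
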