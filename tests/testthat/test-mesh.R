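test_that("triangle quality is 1 for equilateral, 0 for degenerate, sqrt(3)/2 for right isoceles", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(triangle_quality(eq[1, ], eq[2, ], eq[3, ]), 1)
  expect_equal(triangle_quality(c(0, 0), c(1, 1), c(2, 2)), 0)
  expect_equal(triangle_quality(c(1, 1), c(1, 1), c(1, 1)), 0)
  expect_equal(triangle_quality(c(0, 0), c(1, 0), c(0, 1)), sqrt(3) / 2)
})

test_that("quality is invariant under similarity transforms", {
  set.seed(3)
  for (k in 1:20) {
    A <- runif(2); B <- runif(2); C <- runif(2)
    q0 <- triangle_quality(A, B, C)
    th <- runif(1, 0, 2 * pi); s <- runif(1, 0.1, 10); tr <- runif(2, -5, 5)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    f <- function(p) s * as.numeric(Rm %*% p) + tr
    expect_equal(triangle_quality(f(A), f(B), f(C)), q0, tolerance = 1e-12)
    # reflection
    g <- function(p) c(-p[1], p[2])
    expect_equal(triangle_quality(g(A), g(B), g(C)), q0, tolerance = 1e-12)
  }
})

test_that("generated meshes are conforming, high-quality and mirror-symmetric", {
  for (h in c(5.77e-2, 3.46e-2)) {
    mesh <- generate_mesh(domain_spec(), h)
    q <- mesh_quality(mesh)
    expect_gte(min(q), 0.85)
    el <- mesh_edge_lengths(mesh)
    expect_lt(abs(mean(el) - h) / h, 0.1)
    # areas sum to the domain area
    expect_equal(sum(tri_signed_areas(mesh$X, mesh$tri)),
                 2 * 15.96 * 0.15, tolerance = 1e-9)
    # all triangles positively oriented
    expect_true(all(tri_signed_areas(mesh$X, mesh$tri) > 0))
    # exact mirror symmetry of the node set
    mi <- mirror_index(mesh)
    expect_false(anyNA(mi))
    expect_equal(mesh$X[mi, 1], -mesh$X[, 1])
    # boundary tags cover the full boundary length
    ed <- mesh$edges
    len <- sqrt(rowSums((mesh$X[ed$n2, ] - mesh$X[ed$n1, ])^2))
    expect_equal(sum(len), 2 * (2 * 15.96) + 2 * 0.15, tolerance = 1e-9)
  }
  expect_error(generate_mesh(domain_spec(), 0.2), "thickness")
})

test_that("mesh motion preserves orientation and reports inversion", {
  mesh <- generate_mesh(domain_spec(), 0.1)
  n <- nrow(mesh$X)
  m0 <- move_mesh(mesh, matrix(0, n, 2), dt = 1)
  expect_equal(m0$cur, mesh$cur)
  expect_equal(m0$v, matrix(0, n, 2))
  # rigid translation leaves every triangle quality unchanged
  mt <- move_mesh(mesh, cbind(rep(0.3, n), rep(-0.1, n)), dt = 2)
  expect_equal(mesh_quality(mt, current = TRUE), mesh_quality(mesh))
  expect_equal(mt$v[1, ], c(0.15, -0.05))
  # uniform 1% vertical compression scales extents and areas affinely
  du <- cbind(0 * mesh$X[, 1], -0.01 * (mesh$X[, 2] + 0.15))
  mc <- move_mesh(mesh, du, dt = 1)
  expect_equal(diff(range(mc$cur[, 2])), 0.99 * 0.15, tolerance = 1e-12)
  expect_equal(sum(tri_signed_areas(mc$cur, mc$tri)),
               0.99 * 2 * 15.96 * 0.15, tolerance = 1e-9)
  # folding the slab over itself must be refused
  bad <- cbind(0 * mesh$X[, 1], -10 * (mesh$X[, 2] + 0.15))
  expect_null(move_mesh(mesh, bad, dt = 1))
})

test_that("legacy VTK export writes a readable plain-text mesh", {
  mesh <- generate_mesh(domain_spec(), 0.1)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_vtk(mesh, f, point_data = list(N = rep(1, nrow(mesh$X))),
            cell_data = list(W = rep(0, nrow(mesh$tri))))
  txt <- readLines(f)
  expect_equal(txt[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", txt)))
  expect_true(any(grepl("^CELLS", txt)))
  expect_true(any(grepl("SCALARS N", txt)))
  expect_true(any(grepl("SCALARS W", txt)))
})

test_that("wound-run outputs are insensitive to the mesh resolution", {
  # shortened 20-day high-apoptosis runs at two coarse resolutions
  runs <- lapply(c(0.1, 0.07), function(h)
    run_scenario(scenario_preset("high_apoptosis", mesh_edge = h,
                                 duration = 20)))
  a <- utils::tail(runs[[1]]$trace, 1)
  b <- utils::tail(runs[[2]]$trace, 1)
  expect_equal(a$t, 20)
  expect_equal(b$t, 20)
  expect_lt(abs(a$N - b$N) / b$N, 0.02)
  expect_lt(abs(a$M - b$M) / b$M, 0.02)
  expect_lt(abs(a$c - b$c) / b$c, 0.02)
  expect_lt(abs(a$rho - b$rho) / b$rho, 0.02)
  expect_lt(abs(a$thickness - b$thickness) / b$thickness, 0.02)
})
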