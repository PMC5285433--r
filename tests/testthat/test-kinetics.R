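pp <- scar_params()

test_that("fibroblast kinetics match direct evaluation and vanish without cells", {
  expect_equal(reaction_fibroblast(0, 500, 1e-8, pp), 0)
  # forced zero at the unwounded equilibrium
  expect_equal(reaction_fibroblast(pp$N_bar, 0, 0, pp) / pp$N_bar, 0,
               tolerance = 1e-13)
  # independent term-by-term evaluation at a wound-like state
  N <- 5e3; c <- 1e-8
  expected <- 0.924 * (1 + 2 * c / (1e-8 + c)) * (1 - 1e-6 * N) *
    N^(1 + pp$p) - 5.4e6 * c * N - 2e-2 * N
  expect_equal(reaction_fibroblast(N, 0, c, pp), expected)
  expect_error(reaction_fibroblast(-1, 0, 0, pp), "negative")
})

test_that("myofibroblast kinetics require signal and match the arithmetic oracle", {
  expect_equal(reaction_myofibroblast(0, 0, 5e-9, pp), 0)
  expect_equal(reaction_myofibroblast(777, 0, 0, pp), 0)
  # pure differentiation influx: k_F * c * N = 5.4e6 * 1e-8 * 1e4
  expect_equal(reaction_myofibroblast(1e4, 0, 1e-8, pp), 540)
  expect_error(reaction_myofibroblast(1, -1, 0, pp), "negative")
})

test_that("MMP level saturates and is inhibited by the signal", {
  expect_equal(mmp_level(0, 1e-8, 0.1, pp), 0)
  expect_equal(mmp_level(123, 0, 0.2, pp), 123 * 0.2)
  # inhibition factor 1/(1 + 2e8 * 1e-8) = 1/3
  expect_equal(mmp_level(1e4, 1e-8, 0.1, pp), 1e3 / 3)
})

test_that("signal kinetics match independent evaluation and vanish without c", {
  expect_equal(reaction_signal(1e4, 1e3, 0, 0.1, pp), 0)
  expect_equal(reaction_signal(0, 0, 1e-8, 0.1, pp), 0)
  expected <- 2e-9 - 5e-4 * (1e3 / 3) * 1e-8   # secretion minus decay
  expect_equal(reaction_signal(1e4, 0, 1e-8, 0.1, pp), expected)
})

test_that("collagen kinetics match independent evaluation", {
  expect_equal(reaction_collagen(0, 0, 1e-8, 0.1, pp), 0)
  expect_equal(reaction_collagen(pp$N_bar, 0, 0, pp$rho_bar, pp) /
                 (pp$k_rho * pp$N_bar), 0, tolerance = 1e-13)
  N <- 1e4; M <- 1e3; c <- 1e-8; rho <- 0.05
  g <- (N + M) * rho / (1 + 2e8 * c)
  expected <- pp$k_rho * (1 + 10 * c / (1e-9 + c)) * (N + 2 * M) -
    6e-6 * g * rho
  expect_equal(reaction_collagen(N, M, c, rho, pp), expected)
})

test_that("cell and signal fluxes follow their constitutive forms", {
  expect_equal(flux_cells(1e4, 1e4, c(0, 0), c(0, 0), pp), c(0, 0))
  expect_equal(flux_cells(1e4, 2e4, c(0, 0), c(1, 0), pp),
               c(2e-3 * 1e4, 0))
  expect_equal(flux_cells(0, 1e4, c(1, 0), c(0, 0), pp),
               c(-1e-7 * 1e4, 0))
  expect_equal(flux_signal(c(0, 0), pp), c(0, 0))
  expect_equal(flux_signal(c(1, 0), pp), c(-2.9e-3, 0))
  g <- c(0.3, -0.7)
  expect_equal(flux_signal(5 * g, pp), 5 * flux_signal(g, pp))
})

test_that("Patankar split reconstructs the kinetics with non-negative parts", {
  set.seed(7)
  for (k in 1:25) {
    N <- runif(1, 0, 2e4); M <- runif(1, 0, 2e4)
    c <- runif(1, 0, 1e-7); rho <- runif(1, 0, 0.3)
    R <- list(N = reaction_fibroblast(N, M, c, pp),
              M = reaction_myofibroblast(N, M, c, pp),
              c = reaction_signal(N, M, c, rho, pp),
              rho = reaction_collagen(N, M, c, rho, pp))
    z <- c(N = N, M = M, c = c, rho = rho)
    for (f in names(R)) {
      s <- patankar_split(f, N, M, c, rho, pp)
      expect_gte(s$P, 0)
      expect_gte(s$D, 0)
      expect_equal(s$P - s$D * z[[f]], R[[f]], tolerance = 1e-10,
                   label = paste("reconstruction of R_", f))
      # the Patankar update is non-negative for any step size
      for (dt in c(0.1, 10, 1e3))
        expect_gte((z[[f]] + dt * s$P) / (1 + dt * s$D), 0)
    }
  }
})

test_that("pure-decay Patankar update is positive and first-order accurate", {
  pp2 <- scar_params(delta_M = 5e-2)
  s <- patankar_split("M", 0, 1000, 0, 0.1, pp2)
  expect_equal(s$P, 0)
  expect_equal(s$D, 5e-2)
  for (dt in c(0.5, 5, 500))
    expect_gt(1000 / (1 + dt * s$D), 0)
  err <- vapply(c(0.2, 0.1), function(dt) {
    z <- 1000; t <- 0
    while (t < 2 - 1e-12) { z <- z / (1 + dt * s$D); t <- t + dt }
    abs(z - 1000 * exp(-s$D * 2))
  }, 0)
  expect_gt(err[1] / err[2], 1.7)   # halving dt about halves the error
})
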