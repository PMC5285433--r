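# Shared fixtures for the test suite. Long runs are computed once per
# session and reused across test files.

.scar_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .scar_cache))
    assign(name, force(expr), envir = .scar_cache)
  get(name, envir = .scar_cache)
}

# coarse-mesh study runs used by several tests
run_nowound_20d <- function() cached("nowound20", {
  run_scenario(scenario_preset("high_apoptosis", mesh_edge = 0.1,
                               duration = 20), no_wound = TRUE)
})

run_high_400d <- function() cached("high400", {
  run_scenario(scenario_preset("high_apoptosis", mesh_edge = 0.1,
                               duration = 400))
})

run_low_200d <- function() cached("low200", {
  run_scenario(scenario_preset("low_apoptosis", mesh_edge = 0.1,
                               duration = 200))
})

# mirror-pairing of mesh nodes: index of the node at (-Y, Z) for each node
mirror_index <- function(mesh) {
  key <- paste(signif(-mesh$X[, 1], 12), signif(mesh$X[, 2], 12))
  have <- paste(signif(mesh$X[, 1], 12), signif(mesh$X[, 2], 12))
  match(key, have)
}

# independent loop-coded Zalesak limiter used as the FCT oracle
reference_limiter <- function(z_low, z_old, Fdense, m, dt) {
  n <- length(z_low)
  f <- Fdense
  for (i in 1:n) for (j in 1:n)
    if (f[i, j] * (z_low[j] - z_low[i]) > 0) f[i, j] <- 0
  zmax <- zmin <- numeric(n)
  for (i in 1:n) {
    nb <- which(Fdense[i, ] != 0)
    cand_max <- c(max(z_low[i], z_old[i]),
                  vapply(nb, function(j) max(z_low[j], z_old[j]), 0))
    cand_min <- c(min(z_low[i], z_old[i]),
                  vapply(nb, function(j) min(z_low[j], z_old[j]), 0))
    zmax[i] <- max(cand_max); zmin[i] <- min(cand_min)
  }
  Pp <- Pm <- Qp <- Qm <- numeric(n)
  for (i in 1:n) {
    Pp[i] <- sum(pmax(f[i, ], 0)); Pm[i] <- sum(pmin(f[i, ], 0))
    Qp[i] <- m[i] / dt * (zmax[i] - z_low[i])
    Qm[i] <- m[i] / dt * (zmin[i] - z_low[i])
  }
  Rp <- ifelse(Pp > 0, pmin(1, Qp / Pp), 1)
  Rm <- ifelse(Pm < 0, pmin(1, Qm / Pm), 1)
  z <- z_low
  for (i in 1:n) {
    acc <- 0
    for (j in 1:n) {
      if (f[i, j] == 0) next
      a <- if (f[i, j] > 0) min(Rp[i], Rm[j]) else min(Rm[i], Rp[j])
      acc <- acc + a * f[i, j]
    }
    z[i] <- z_low[i] + dt / m[i] * acc
  }
  z
}

# stress / energy oracle from the deformation gradient F2 (plane strain):
# B3 = blockdiag(F2 F2', 1), J = det(F2); an independent derivation path
# from the displacement-gradient route used by the implementation
oracle_stress <- function(F2, rho, params) {
  B2 <- F2 %*% t(F2)
  J <- det(F2)
  E <- params$E_I * sqrt(rho)
  twoC1 <- E / (2 * (1 + params$nu))
  twoD1 <- E / (3 * (1 - 2 * params$nu))
  trB3 <- sum(diag(B2)) + 1
  (twoD1 * J * (J - 1) * diag(2) +
      twoC1 * J^(-2 / 3) * (B2 - trB3 / 3 * diag(2))) / J
}

oracle_energy <- function(F2, rho, params) {
  B2 <- F2 %*% t(F2)
  J <- det(F2)
  E <- params$E_I * sqrt(rho)
  E / (4 * (1 + params$nu)) * (J^(-2 / 3) * (sum(diag(B2)) + 1) - 3) +
    E / (6 * (1 - 2 * params$nu)) * (J - 1)^2
}

# Eulerian displacement gradient corresponding to a deformation gradient
grad_u_from_F <- function(F2) diag(2) - solve(F2)
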