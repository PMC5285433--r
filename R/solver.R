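#' Solver control settings
#'
#' Tunable tolerances and step-size bounds for the segregated
#' defect-correction time stepper.
#'
#' @param dt0 initial step, day. @param dt_min,dt_max step bounds, day.
#' @param tol_lte relative local-truncation-error tolerance of the adaptive
#'   controller.
#' @param safety,shrink_min,grow_max controller safety factor and step
#'   change clamps.
#' @param tol_fp relative inter-iterate tolerance of the fixed-point
#'   (defect-correction) loop. @param max_fp iteration cap.
#' @param tol_mech mechanics Newton relative residual tolerance.
#' @param mech_max_it mechanics Newton iteration cap.
#' @return a list of class `scar_control`.
#' @export
solver_control <- function(dt0 = 1e-2, dt_min = 1e-8, dt_max = 5,
                           tol_lte = 1e-3, safety = 0.9, shrink_min = 0.1,
                           grow_max = 2, tol_fp = 1e-6, max_fp = 25L,
                           tol_mech = 1e-8, mech_max_it = 30L) {
  stopifnot(dt0 > 0, dt_min > 0, dt_max >= dt0, tol_lte > 0, tol_fp > 0)
  structure(list(dt0 = dt0, dt_min = dt_min, dt_max = dt_max,
                 tol_lte = tol_lte, safety = safety,
                 shrink_min = shrink_min, grow_max = grow_max,
                 tol_fp = tol_fp, max_fp = max_fp, tol_mech = tol_mech,
                 mech_max_it = mech_max_it), class = "scar_control")
}

# Dirichlet node set for the constituents: lateral boundaries B.II / B.IV
dirichlet_nodes <- function(mesh) {
  ed <- mesh$edges
  sort(unique(c(ed$n1[ed$tag %in% c("B.II", "B.IV")],
                ed$n2[ed$tag %in% c("B.II", "B.IV")])))
}

#' Assemble and solve the backward-Euler transport update of one constituent
#'
#' Moving-grid (Lagrangian) lumped-mass backward Euler: because the mesh
#' convects with the material, the advective term is absorbed into the
#' change of the mass matrix between the old and the new configuration,
#' and only diffusion, chemotaxis and reactions remain:
#' `(m_new/dt + m_new D - L) z_low = m_old z_old / dt + m_new P`,
#' where `L = K + D_art` is the low-order (positivity-preserving) operator
#' obtained from the Galerkin transport operator `K` by discrete
#' upwinding, and `(P, D)` is the Patankar production/destruction split of
#' the reactions. Dirichlet rows on the lateral boundaries are imposed
#' exactly, and the limited antidiffusive fluxes (consistent-mass and
#' upwinding corrections) are added by the Zalesak limiter. All assembly
#' happens on the pattern cached per mesh.
#' @keywords internal
transport_step <- function(tp, tg, kvals_elem, P, D, dval, m_old, z_old,
                           dt) {
  kv <- as.numeric(tp$Agg %*% kvals_elem)
  off <- tp$off
  dv <- numeric(tp$np)
  dv[off] <- pmax(pmax(-kv[off], -kv[tp$tt[off]]), 0)
  dv[tp$dslot] <- -as.numeric(tp$AggDi %*% dv[off])
  av <- -(kv + dv)
  av[tp$dslot] <- av[tp$dslot] + tg$m_new / dt + tg$m_new * D
  rhs <- m_old * z_old / dt + tg$m_new * P
  av[tp$dir_slots] <- 0
  av[tp$dslot[tp$dir]] <- 1
  rhs[tp$dir] <- dval
  A <- sparseMatrix(i = tp$pat_i, j = tp$pat_j, x = av,
                    dims = c(tp$n, tp$n))
  z_low <- pmax(as.numeric(solve(A, rhs)), 0)
  # flux correction on the free off-diagonal pattern
  of <- tp$off_free
  io <- tp$pat_i[of]; jo <- tp$pat_j[of]
  zdot <- (z_low - z_old) / dt
  f <- tg$mc[of] * (zdot[io] - zdot[jo]) + dv[of] * (z_low[io] - z_low[jo])
  z <- pmax(fct_core(io, jo, f, z_low, z_old, tg$m_new, dt, tp)$z, 0)
  z[tp$dir] <- dval
  z
}

# advance the four constituents on a given end-of-step mesh (one inner
# defect-correction pass); fields of `guess` provide the lagged
# coefficients, `old` the previous time level
advance_constituents <- function(mesh_new, m_old, old, guess, params, dt) {
  tri <- mesh_new$tri
  tp <- transport_cache(mesh_new)
  tg <- transport_geometry(mesh_new, tp)
  Ng <- pmax(guess$N, 0); Mg <- pmax(guess$M, 0)
  cg <- pmax(guess$c, 0); rg <- pmax(guess$rho, 0)
  Fg <- Ng + Mg
  F_e <- (Fg[tri[, 1]] + Fg[tri[, 2]] + Fg[tri[, 3]]) / 3
  grad_c <- recover_gradient(mesh_new, guess$c)
  chem <- chemo_values(tg$geom, tri, tp, grad_c, params$chi_F)

  sN <- patankar_split("N", Ng, Mg, cg, rg, params)
  sM <- patankar_split("M", Ng, Mg, cg, rg, params)
  sc <- patankar_split("c", Ng, Mg, cg, rg, params)
  sr <- patankar_split("rho", Ng, Mg, cg, rg, params)

  k_cells <- -rep(params$D_F * F_e, 9L) * tg$gprod + chem
  k_signal <- -params$D_c * tg$gprod
  N <- transport_step(tp, tg, k_cells, sN$P, sN$D, params$N_bar,
                      m_old, old$N, dt)
  M <- transport_step(tp, tg, k_cells, sM$P, sM$D, params$M_bar,
                      m_old, old$M, dt)
  c_ <- transport_step(tp, tg, k_signal, sc$P, sc$D, params$c_bar,
                       m_old, old$c, dt)
  # collagen: no flux term; per-node ODE with the Lagrangian mass ratio
  rho <- (m_old * old$rho + dt * tg$m_new * sr$P) /
    (tg$m_new * (1 + dt * sr$D))
  list(N = N, M = M, c = c_, rho = rho)
}

state_scales <- function(params) {
  c(N = params$N_bar, M = params$N_bar,
    c = max(params$c_w, 1e-300), rho = params$rho_bar)
}

#' One adaptive segregated step (defect correction)
#'
#' Attempts a single backward-Euler step of size `dt`: iterates
#' (1) constituents on the current end-of-step mesh, (2) quasi-static
#' mechanics from the updated myofibroblast and collagen fields,
#' (3) mesh motion by the displacement increment, until the relative
#' inter-iterate change falls below `tol_fp`. Non-convergence, element
#' inversion or a failed mechanics solve are reported as a rejection; the
#' driver halves the step.
#'
#' @param state current `scar_state` (fields on `mesh`).
#' @param mesh current `scar_mesh` (its `cur` coordinates are `X +
#'   state$u`).
#' @param params a [scar_params()] set.
#' @param dt trial step size, day.
#' @param control a [solver_control()].
#' @return list: `accepted` (fixed-point converged), `state`, `mesh`,
#'   `fp_iterations`, `fp_delta`, `mech_iterations`.
#' @export
defect_correction_step <- function(state, mesh, params, dt, control) {
  n <- n_nodes(mesh)
  geom_old <- fem_geom(mesh$cur, mesh$tri)
  m_old <- mass_lumped(geom_old, mesh$tri, n)
  old <- state
  guess <- state
  u_prev <- state$u
  scl <- state_scales(params)
  mech_its <- 0L
  mesh_k <- mesh
  for (it in seq_len(control$max_fp)) {
    fields <- advance_constituents(mesh_k, m_old, old, guess, params, dt)
    mech <- solve_mechanics(mesh_k, fields$M, fields$rho, params,
                            u0 = guess$u, tol = control$tol_mech,
                            max_it = control$mech_max_it)
    if (!mech$converged)
      return(list(accepted = FALSE, reason = "mechanics"))
    mech_its <- mech_its + mech$iterations
    du <- mech$u - (mesh_k$cur - mesh_k$X)
    mesh_try <- move_mesh(mesh_k, du, dt)
    if (is.null(mesh_try))
      return(list(accepted = FALSE, reason = "inversion"))
    mesh_k <- mesh_try
    delta <- max(
      max(abs(fields$N - guess$N)) / scl["N"],
      max(abs(fields$M - guess$M)) / scl["M"],
      max(abs(fields$c - guess$c)) / scl["c"],
      max(abs(fields$rho - guess$rho)) / scl["rho"],
      max(abs(mech$u - guess$u)) / mesh$domain$thickness
    )
    guess$N <- fields$N; guess$M <- fields$M
    guess$c <- fields$c; guess$rho <- fields$rho
    guess$u <- mech$u
    if (delta < control$tol_fp) {
      guess$t <- old$t + dt
      guess$v <- (mech$u - u_prev) / dt
      return(list(accepted = TRUE, state = guess, mesh = mesh_k,
                  fp_iterations = it, fp_delta = delta,
                  mech_iterations = mech_its))
    }
  }
  list(accepted = FALSE, reason = "fixed-point")
}

#' Adaptive step-size controller
#'
#' Accepts the step iff the local-truncation-error estimate does not
#' exceed the tolerance, and proposes
#' `dt_new = dt * clip(safety * sqrt(tol/est), shrink_min, grow_max)`;
#' a zero estimate grows the step by the maximum factor.
#'
#' @param est non-negative relative error estimate.
#' @param dt current step, day.
#' @param control a [solver_control()].
#' @return list `accept`, `dt_new`.
#' @export
adapt_timestep <- function(est, dt, control) {
  if (est < 0 || !is.finite(est)) stop("error estimate must be finite and >= 0")
  fac <- if (est == 0) control$grow_max else
    min(max(control$safety * sqrt(control$tol_lte / est),
            control$shrink_min), control$grow_max)
  list(accept = est <= control$tol_lte,
       dt_new = min(max(dt * fac, control$dt_min), control$dt_max))
}

# second-divided-difference curvature of the constituent fields, used both
# for the LTE estimate and for the Kavetski-style local extrapolation
lte_curvature <- function(cur, prev, prev2, dt, dt_prev) {
  lapply(c(N = "N", M = "M", c = "c", rho = "rho"), function(f) {
    2 * ((cur[[f]] - prev[[f]]) / dt - (prev[[f]] - prev2[[f]]) / dt_prev) /
      (dt + dt_prev)
  })
}

#' Run the coupled simulation over a time interval
#'
#' Advances the full segregated solver from `state` to `t_end` with
#' adaptive step-size control. After each accepted step a local
#' extrapolation (one-step Richardson correction built from the two most
#' recent solutions) sharpens the constituent fields; the correction is
#' clipped at zero so positivity survives. Displacement is not
#' extrapolated (the mechanics is quasi-static and recomputed each step).
#'
#' @param mesh a `scar_mesh`.
#' @param state initial `scar_state`.
#' @param params a [scar_params()] set.
#' @param t_end final time, day.
#' @param control a [solver_control()].
#' @param record optional `function(state, mesh)` called after every
#'   accepted step; its results are collected in the returned `records`.
#' @param verbose print per-step progress.
#' @return list with final `state`, `mesh`, a `report` data frame (one row
#'   per accepted step: time, dt, fixed-point iterations, minima of the
#'   four fields, rejected-step count) and `records`.
#' @export
run_simulation <- function(mesh, state, params, t_end,
                           control = solver_control(), record = NULL,
                           verbose = FALSE) {
  dt <- control$dt0
  prev <- NULL; dt_prev <- NA_real_
  rows <- list(); recs <- list(); rejected_total <- 0L
  scl <- state_scales(params)
  dir <- dirichlet_nodes(mesh)
  step <- 0L
  while (state$t < t_end - 1e-12) {
    dt <- min(dt, t_end - state$t)
    res <- defect_correction_step(state, mesh, params, dt, control)
    if (!res$accepted) {
      rejected_total <- rejected_total + 1L
      dt <- dt / 2
      if (dt < control$dt_min)
        stop("simulation aborted at t = ", state$t,
             ": step size underflow (", res$reason, ")")
      next
    }
    # local truncation error estimate by comparison with the locally
    # extrapolated (second-order) solution
    if (!is.null(prev)) {
      curv <- lte_curvature(res$state, state, prev, dt, dt_prev)
      est <- max(vapply(names(curv), function(f)
        max(abs(curv[[f]])) * dt^2 / 2 / scl[[f]], 0))
    } else est <- 0
    ad <- adapt_timestep(est, dt, control)
    if (!ad$accept) {
      rejected_total <- rejected_total + 1L
      dt <- ad$dt_new
      if (dt <= control$dt_min)
        stop("simulation aborted at t = ", state$t,
             ": adaptive controller underflow")
      next
    }
    new_state <- res$state
    if (!is.null(prev)) {
      for (f in c("N", "M", "c", "rho")) {
        corr <- new_state[[f]] - dt^2 / 2 * curv[[f]]
        corr <- pmax(corr, 0)
        if (f != "rho" && length(dir))
          corr[dir] <- new_state[[f]][dir]
        new_state[[f]] <- corr
      }
    }
    prev <- state; dt_prev <- dt
    state <- new_state; mesh <- res$mesh
    step <- step + 1L
    rows[[step]] <- data.frame(
      t = state$t, dt = dt, fp_iterations = res$fp_iterations,
      mech_iterations = res$mech_iterations,
      min_N = min(state$N), min_M = min(state$M),
      min_c = min(state$c), min_rho = min(state$rho),
      rejected = rejected_total)
    if (!is.null(record)) recs[[step]] <- record(state, mesh)
    if (verbose)
      message(sprintf("t = %8.3f  dt = %8.4f  fp = %d", state$t, dt,
                      res$fp_iterations))
    dt <- ad$dt_new
  }
  list(state = state, mesh = mesh, report = do.call(rbind, rows),
       records = recs)
}
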