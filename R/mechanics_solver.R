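# Quasi-static finite-strain mechanics solve.
#
# Weak form of -div(sigma) = div(psi) with Robin spring boundary data:
#   int sigma(u):grad(phi) dx + spring terms
#     + int psi:grad(phi) dx - bnd int (n.psi).phi ds = 0,
# assembled on the current (deformed) configuration x = X + u. The tangent
# is built by forward finite differences of the fully local element/edge
# residuals, which captures material and geometric stiffness together.

# per-element residuals: ue is m x 6 local dofs (uy1,uz1,uy2,uz2,uy3,uz3),
# Xe m x 6 reference coords, psi_v m x 3 nodal traction stress values
mech_elem_resid <- function(ue, Xe, rho_e, psi_v, params) {
  cy1 <- Xe[, 1] + ue[, 1]; cz1 <- Xe[, 2] + ue[, 2]
  cy2 <- Xe[, 3] + ue[, 3]; cz2 <- Xe[, 4] + ue[, 4]
  cy3 <- Xe[, 5] + ue[, 5]; cz3 <- Xe[, 6] + ue[, 6]
  twoA <- (cy2 - cy1) * (cz3 - cz1) - (cy3 - cy1) * (cz2 - cz1)
  ok <- twoA > 0
  by1 <- (cz2 - cz3) / twoA; by2 <- (cz3 - cz1) / twoA; by3 <- (cz1 - cz2) / twoA
  bz1 <- (cy3 - cy2) / twoA; bz2 <- (cy1 - cy3) / twoA; bz3 <- (cy2 - cy1) / twoA
  g11 <- ue[, 1] * by1 + ue[, 3] * by2 + ue[, 5] * by3
  g12 <- ue[, 1] * bz1 + ue[, 3] * bz2 + ue[, 5] * bz3
  g21 <- ue[, 2] * by1 + ue[, 4] * by2 + ue[, 6] * by3
  g22 <- ue[, 2] * bz1 + ue[, 4] * bz2 + ue[, 6] * bz3
  s <- stress_elems(g11, g12, g21, g22, rho_e, params)
  ok <- ok & s$ok
  A <- twoA / 2
  psibar <- rowMeans(psi_v)
  sy <- s$s11 + psibar; sz <- s$s22 + psibar
  r <- cbind(A * (sy * by1 + s$s12 * bz1), A * (s$s12 * by1 + sz * bz1),
             A * (sy * by2 + s$s12 * bz2), A * (s$s12 * by2 + sz * bz2),
             A * (sy * by3 + s$s12 * bz3), A * (s$s12 * by3 + sz * bz3))
  list(r = r, ok = ok)
}

# per-edge residuals: spring tractions and the boundary part of psi.
# ue m x 4 (uy1,uz1,uy2,uz2); kind: 1 spring-in-z (bottom), 2 spring-in-y
# (lateral), 0 none (top); s_coef spring constant; rho_v / psi_v m x 2
mech_edge_resid <- function(ue, Xe, rho_v, psi_v, s_coef, kind) {
  cy1 <- Xe[, 1] + ue[, 1]; cz1 <- Xe[, 2] + ue[, 2]
  cy2 <- Xe[, 3] + ue[, 3]; cz2 <- Xe[, 4] + ue[, 4]
  dy <- cy2 - cy1; dz <- cz2 - cz1
  len <- sqrt(dy^2 + dz^2)
  ny <- dz / len; nz <- -dy / len    # outward for counterclockwise edges
  q <- edge_gauss2()
  r <- matrix(0, nrow(ue), 4L)
  for (k in 1:2) {
    t <- q$t[k]; w <- q$w[k]
    ph1 <- 1 - t; ph2 <- t
    rho_q <- ph1 * rho_v[, 1] + ph2 * rho_v[, 2]
    psi_q <- ph1 * psi_v[, 1] + ph2 * psi_v[, 2]
    uy_q <- ph1 * ue[, 1] + ph2 * ue[, 3]
    uz_q <- ph1 * ue[, 2] + ph2 * ue[, 4]
    if (kind == 1L) {           # opposing spring in z on the deformed edge
      f <- s_coef * rho_q * uz_q
      r[, 2] <- r[, 2] + w * len * f * ph1
      r[, 4] <- r[, 4] + w * len * f * ph2
    } else if (kind == 2L) {    # opposing spring in y
      f <- s_coef * rho_q * uy_q
      r[, 1] <- r[, 1] + w * len * f * ph1
      r[, 3] <- r[, 3] + w * len * f * ph2
    }
    # - bnd int (n.psi).phi ds  (psi isotropic)
    r[, 1] <- r[, 1] - w * len * psi_q * ny * ph1
    r[, 2] <- r[, 2] - w * len * psi_q * nz * ph1
    r[, 3] <- r[, 3] - w * len * psi_q * ny * ph2
    r[, 4] <- r[, 4] - w * len * psi_q * nz * ph2
  }
  r
}

edge_kind <- function(tag) c("B.I" = 1L, "B.II" = 2L, "B.III" = 0L,
                             "B.IV" = 2L)[[tag]]

# u-independent mechanics setup, cached per mesh
mech_cache <- function(mesh, params) {
  env <- mesh_cache_env(mesh)
  if (!is.null(env$mc)) return(env$mc)
  tri <- mesh$tri; X <- mesh$X; ed <- mesh$edges
  kinds <- vapply(ed$tag, edge_kind, 0L)
  env$mc <- list(
    tri = tri,
    Xe = cbind(X[tri[, 1], 1], X[tri[, 1], 2], X[tri[, 2], 1],
               X[tri[, 2], 2], X[tri[, 3], 1], X[tri[, 3], 2]),
    Xed = cbind(X[ed$n1, 1], X[ed$n1, 2], X[ed$n2, 1], X[ed$n2, 2]),
    n1 = ed$n1, n2 = ed$n2,
    kinds = kinds,
    scoefs = ifelse(kinds == 1L, params$s1,
                    ifelse(kinds == 2L, params$s2, 0)),
    kind_sets = lapply(sort(unique(kinds)), function(kk) which(kinds == kk)),
    gdof_tri = cbind(2L * tri[, 1] - 1L, 2L * tri[, 1], 2L * tri[, 2] - 1L,
                     2L * tri[, 2], 2L * tri[, 3] - 1L, 2L * tri[, 3]),
    gdof_ed = cbind(2L * ed$n1 - 1L, 2L * ed$n1, 2L * ed$n2 - 1L,
                    2L * ed$n2)
  )
  env$mc
}

# full residual and (optionally) FD tangent for nodal displacement u (n x 2)
mech_system <- function(u, mesh, rho, psi, params, want_tangent = TRUE,
                        h_fd = 1e-7) {
  n <- nrow(mesh$X)
  mc <- mech_cache(mesh, params)
  tri <- mc$tri
  Xe <- mc$Xe
  ue <- cbind(u[tri[, 1], 1], u[tri[, 1], 2], u[tri[, 2], 1], u[tri[, 2], 2],
              u[tri[, 3], 1], u[tri[, 3], 2])
  rho_e <- (rho[tri[, 1]] + rho[tri[, 2]] + rho[tri[, 3]]) / 3
  psi_v <- cbind(psi[tri[, 1]], psi[tri[, 2]], psi[tri[, 3]])
  base <- mech_elem_resid(ue, Xe, rho_e, psi_v, params)
  if (!all(base$ok)) return(list(ok = FALSE))

  Xed <- mc$Xed
  ued <- cbind(u[mc$n1, 1], u[mc$n1, 2], u[mc$n2, 1], u[mc$n2, 2])
  rho_vd <- cbind(rho[mc$n1], rho[mc$n2])
  psi_vd <- cbind(psi[mc$n1], psi[mc$n2])
  edge_res <- function(uu) {
    out <- matrix(0, length(mc$n1), 4L)
    for (sel in mc$kind_sets) {
      out[sel, ] <- mech_edge_resid(uu[sel, , drop = FALSE],
                                    Xed[sel, , drop = FALSE],
                                    rho_vd[sel, , drop = FALSE],
                                    psi_vd[sel, , drop = FALSE],
                                    mc$scoefs[sel][1], mc$kinds[sel][1])
    }
    out
  }
  base_e <- edge_res(ued)

  # scatter: element local dof -> global dof (y_i -> 2i-1, z_i -> 2i)
  gdof_tri <- mc$gdof_tri
  gdof_ed <- mc$gdof_ed
  r <- numeric(2L * n)
  for (a in 1:6) r <- r + tabulate0(gdof_tri[, a], base$r[, a], 2L * n)
  for (a in 1:4) r <- r + tabulate0(gdof_ed[, a], base_e[, a], 2L * n)
  if (!want_tangent) return(list(ok = TRUE, r = r))

  ii <- jj <- xx <- list(); k <- 0L
  for (b in 1:6) {
    up <- ue; up[, b] <- up[, b] + h_fd
    pert <- mech_elem_resid(up, Xe, rho_e, psi_v, params)
    dr <- (pert$r - base$r) / h_fd
    for (a in 1:6) {
      k <- k + 1L
      ii[[k]] <- gdof_tri[, a]; jj[[k]] <- gdof_tri[, b]; xx[[k]] <- dr[, a]
    }
  }
  for (b in 1:4) {
    up <- ued; up[, b] <- up[, b] + h_fd
    dr <- (edge_res(up) - base_e) / h_fd
    for (a in 1:4) {
      k <- k + 1L
      ii[[k]] <- gdof_ed[, a]; jj[[k]] <- gdof_ed[, b]; xx[[k]] <- dr[, a]
    }
  }
  Ktan <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(2L * n, 2L * n))
  list(ok = TRUE, r = r, K = Ktan)
}

#' Solve the quasi-static mechanics for the displacement field
#'
#' Damped Newton iteration on the finite-strain weak form, driven by the
#' myofibroblast traction stress `psi(M, rho)` and restrained by the
#' collagen-proportional boundary springs. If the full-load Newton fails to
#' converge, the traction is applied in increasing increments
#' (load stepping) with warm starts. With `M = 0` everywhere the solution
#' is exactly `u = 0`.
#'
#' @param mesh a `scar_mesh` (reference coordinates are used; the deformed
#'   configuration is `X + u`).
#' @param M,rho nodal myofibroblast density and collagen concentration.
#' @param params a [scar_params()] set.
#' @param u0 initial guess, n x 2 (defaults to zero).
#' @param tol relative residual tolerance.
#' @param max_it Newton iteration cap per load level.
#' @return list with `u` (n x 2), `converged`, `iterations`, `residual`;
#'   `converged = FALSE` signals the time controller to reject the step.
#' @export
solve_mechanics <- function(mesh, M, rho, params, u0 = NULL,
                            tol = 1e-8, max_it = 30L) {
  n <- nrow(mesh$X)
  psi_full <- traction_stress(pmax(M, 0), pmax(rho, 0), params)
  u <- if (is.null(u0)) matrix(0, n, 2) else u0
  # force scale for the absolute convergence floor
  g0 <- fem_geom(mesh$X, mesh$tri)
  fscale <- max(sum(abs(g0$area) *
                      abs(psi_full[mesh$tri[, 1]] + psi_full[mesh$tri[, 2]] +
                            psi_full[mesh$tri[, 3]]) / 3) / 0.15,
                params$E_I * sqrt(max(params$rho_bar, 1e-6)) * 1e-3)
  newton <- function(u, psi) {
    it <- 0L; rnorm0 <- NA_real_
    repeat {
      # residual first: skip the tangent assembly if already converged
      sys0 <- mech_system(u, mesh, rho, psi, params, want_tangent = FALSE)
      if (!sys0$ok) return(list(u = u, converged = FALSE, it = it,
                                res = Inf))
      rn <- sqrt(sum(sys0$r^2))
      if (it == 0L) rnorm0 <- max(rn, fscale * 1e-30)
      if (rn <= tol * max(rnorm0, fscale) || rn == 0)
        return(list(u = u, converged = TRUE, it = it, res = rn))
      if (it >= max_it) return(list(u = u, converged = FALSE, it = it,
                                    res = rn))
      sys <- mech_system(u, mesh, rho, psi, params)
      du <- tryCatch(
        matrix(as.numeric(solve(sys$K, -sys$r)), ncol = 2, byrow = TRUE),
        error = function(e) NULL)
      if (is.null(du)) return(list(u = u, converged = FALSE, it = it,
                                   res = rn))
      # damped update: halve until the residual decreases
      step <- 1; accepted <- FALSE
      for (ls in 1:10) {
        u_try <- u + step * du
        s2 <- mech_system(u_try, mesh, rho, psi, params,
                          want_tangent = FALSE)
        if (s2$ok && sqrt(sum(s2$r^2)) < rn) {
          u <- u_try; accepted <- TRUE; break
        }
        step <- step / 2
      }
      if (!accepted) return(list(u = u, converged = FALSE, it = it,
                                 res = rn))
      it <- it + 1L
    }
  }
  out <- newton(u, psi_full)
  if (!out$converged) {
    # load stepping: ramp the traction up in increments, warm-starting
    u <- if (is.null(u0)) matrix(0, n, 2) else u0
    for (lam in c(0.25, 0.5, 0.75, 1)) {
      out <- newton(u, lam * psi_full)
      if (!out$converged) break
      u <- out$u
    }
  }
  list(u = out$u, converged = out$converged, iterations = out$it,
       residual = out$res)
}
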