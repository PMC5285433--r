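#' Finite-strain constitutive relations
#'
#' The dermal layer is a heterogeneous, isotropic, compressible neo-Hookean
#' solid under plane strain in the (y, z) cross-section. From the Eulerian
#' displacement gradient `G = grad(u)` the Eulerian strain is
#' `e = (G + G' - G'G)/2`, the left Cauchy--Green tensor is
#' `B = (I - 2e)^(-1)` and `J = sqrt(det B)`. The Cauchy stress follows
#' `J sigma = 2 D1 J (J - 1) I + 2 C1 J^(-2/3) (B - tr(B)/3 I)` with
#' collagen-dependent moduli `2C1 = E(rho)/(2(1+nu))`,
#' `2D1 = E(rho)/(3(1-2nu))` and `E(rho) = E_I sqrt(rho)`. Plane strain is
#' enforced by a zero out-of-plane strain, so `B_33 = 1` and the
#' out-of-plane normal stress is computed but does no work.
#'
#' @name constitutive
NULL

# kinematics common to stress and energy; grad_u is a 2x2 matrix
plane_strain_kinematics <- function(grad_u) {
  stopifnot(is.matrix(grad_u), all(dim(grad_u) == c(2L, 2L)))
  e2 <- 0.5 * (grad_u + t(grad_u) - t(grad_u) %*% grad_u)
  C2 <- diag(2) - 2 * e2            # in-plane block of I - 2e
  dC <- C2[1, 1] * C2[2, 2] - C2[1, 2] * C2[2, 1]
  if (dC <= 0 || (C2[1, 1] + C2[2, 2]) <= 0)
    stop("inadmissible deformation: I - 2e is not positive definite")
  B2 <- matrix(c(C2[2, 2], -C2[2, 1], -C2[1, 2], C2[1, 1]), 2, 2) / dC
  list(B2 = B2, J = 1 / sqrt(dC), trB3 = B2[1, 1] + B2[2, 2] + 1)
}

#' Cauchy stress of the collagen-dependent neo-Hookean dermis
#'
#' @param grad_u 2x2 Eulerian displacement gradient in the (y, z) plane
#'   (dimensionless).
#' @param rho collagen concentration, g/cm^3.
#' @param params a [scar_params()] set.
#' @return list with `sigma` (in-plane 2x2 Cauchy stress, N/cm^2),
#'   `sigma_out` (out-of-plane normal component) and `J` (volume ratio).
#' @export
cauchy_stress <- function(grad_u, rho, params) {
  if (rho < 0) stop("negative value supplied for rho")
  k <- plane_strain_kinematics(grad_u)
  E <- params$E_I * sqrt(rho)
  twoC1 <- E / (2 * (1 + params$nu))
  twoD1 <- E / (3 * (1 - 2 * params$nu))
  J <- k$J
  vol <- twoD1 * J * (J - 1)
  dev_fac <- twoC1 * J^(-2 / 3)
  Jsig <- vol * diag(2) + dev_fac * (k$B2 - k$trB3 / 3 * diag(2))
  Jsig_out <- vol + dev_fac * (1 - k$trB3 / 3)
  list(sigma = Jsig / J, sigma_out = Jsig_out / J, J = J)
}

#' Myofibroblast traction stress
#'
#' The pulling of the myofibroblast population on the matrix is an isotropic
#' stress `psi = xi M rho / (R^2 + rho^2) I`; the body force in the force
#' balance is its divergence (assembled weakly by the solver). For fixed `M`
#' the magnitude is maximal at `rho = R` where it equals `xi M / (2 R)`.
#'
#' @param M myofibroblast density, cells/cm^3.
#' @param rho collagen concentration, g/cm^3.
#' @param params a [scar_params()] set.
#' @return scalar (vectorized) isotropic stress magnitude, N/cm^2.
#' @export
traction_stress <- function(M, rho, params) {
  check_nonneg(M = M, rho = rho)
  params$xi * M * rho / (params$R^2 + rho^2)
}

#' Strain energy density
#'
#' `W = C1 (Ibar1 - 3) + D1 (J - 1)^2` with the isochoric first invariant
#' `Ibar1 = J^(-2/3) tr(B)`; zero at zero deformation and non-negative for
#' admissible deformations. Used as the measure of wound compaction.
#'
#' @inheritParams cauchy_stress
#' @return scalar energy density per unit current volume in the package's
#'   stress units (N/cm^2, i.e. N cm per cm^3); multiply by 0.01 to convert
#'   to J/cm^3 (done by [strain_energy_field()] for reporting).
#' @export
strain_energy <- function(grad_u, rho, params) {
  if (rho < 0) stop("negative value supplied for rho")
  k <- plane_strain_kinematics(grad_u)
  E <- params$E_I * sqrt(rho)
  C1 <- E / (4 * (1 + params$nu))
  D1 <- E / (6 * (1 - 2 * params$nu))
  Ibar1 <- k$J^(-2 / 3) * k$trB3
  C1 * (Ibar1 - 3) + D1 * (k$J - 1)^2
}

# ---- vectorized element-level versions used by the FEM solver ----
# gu components are vectors over elements: g11 = d u_y/d y, g12 = d u_y/d z,
# g21 = d u_z/d y, g22 = d u_z/d z. Returns per-element stress components or
# NA admissibility flag (no error: the caller treats it as step rejection).
stress_elems <- function(g11, g12, g21, g22, rho_e, params) {
  # e = (G + G' - G'G)/2, C = I - 2e
  e11 <- g11 - 0.5 * (g11 * g11 + g21 * g21)
  e22 <- g22 - 0.5 * (g12 * g12 + g22 * g22)
  e12 <- 0.5 * (g12 + g21) - 0.5 * (g11 * g12 + g21 * g22)
  C11 <- 1 - 2 * e11; C22 <- 1 - 2 * e22; C12 <- -2 * e12
  dC <- C11 * C22 - C12 * C12
  ok <- dC > 0 & (C11 + C22) > 0
  B11 <- C22 / dC; B22 <- C11 / dC; B12 <- -C12 / dC
  J <- 1 / sqrt(dC)
  trB3 <- B11 + B22 + 1
  E <- params$E_I * sqrt(pmax(rho_e, 0))
  twoC1 <- E / (2 * (1 + params$nu))
  twoD1 <- E / (3 * (1 - 2 * params$nu))
  vol <- twoD1 * J * (J - 1)
  dev_fac <- twoC1 * J^(-2 / 3)
  s11 <- (vol + dev_fac * (B11 - trB3 / 3)) / J
  s22 <- (vol + dev_fac * (B22 - trB3 / 3)) / J
  s12 <- (dev_fac * B12) / J
  s33 <- (vol + dev_fac * (1 - trB3 / 3)) / J
  list(s11 = s11, s22 = s22, s12 = s12, s33 = s33, J = J, ok = ok,
       B11 = B11, B22 = B22, trB3 = trB3)
}

energy_elems <- function(g11, g12, g21, g22, rho_e, params) {
  s <- stress_elems(g11, g12, g21, g22, rho_e, params)
  E <- params$E_I * sqrt(pmax(rho_e, 0))
  C1 <- E / (4 * (1 + params$nu))
  D1 <- E / (6 * (1 - 2 * params$nu))
  Ibar1 <- s$J^(-2 / 3) * s$trB3
  W <- C1 * (Ibar1 - 3) + D1 * (s$J - 1)^2
  W[!s$ok] <- NA_real_
  W
}
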