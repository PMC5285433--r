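#' Pointwise reaction kinetics and constitutive fluxes
#'
#' These functions evaluate, at a material point, every right-hand-side term
#' of the coupled model: net reaction rates for the four constituents, the
#' generic-MMP level that mediates proteolysis, and the cell/signal fluxes.
#' All are vectorized over their field arguments and reject negative
#' densities/concentrations (the solver applies its own non-negativity
#' guards before calling them).
#'
#' @name kinetics
NULL

check_nonneg <- function(...) {
  vals <- list(...)
  for (nm in names(vals))
    if (any(vals[[nm]] < 0, na.rm = TRUE))
      stop("negative value supplied for ", nm)
  invisible(TRUE)
}

#' Fibroblast net reaction rate
#'
#' Adjusted logistic division (enhanced by the signaling molecule), loss to
#' differentiation into myofibroblasts, and apoptosis:
#' `R_N = r_F (1 + r_F_max c/(a_c_I + c)) (1 - kappa_F (N+M)) N^(1+p)
#'        - k_F c N - delta_N N`.
#'
#' @param N,M fibro-/myofibroblast densities, cells/cm^3.
#' @param c signaling molecule concentration, g/cm^3.
#' @param params a [scar_params()] set.
#' @return net rate, cells/(cm^3 day).
#' @export
reaction_fibroblast <- function(N, M, c, params) {
  check_nonneg(N = N, M = M, c = c)
  F <- N + M
  params$r_F * (1 + params$r_F_max * c / (params$a_c_I + c)) *
    (1 - params$kappa_F * F) * N^(1 + params$p) -
    params$k_F * c * N - params$delta_N * N
}

#' Myofibroblast net reaction rate
#'
#' Myofibroblasts divide only in the presence of the signaling molecule,
#' gain cells from fibroblast differentiation, and undergo apoptosis:
#' `R_M = r_F ((1+r_F_max) c/(a_c_I + c)) (1 - kappa_F (N+M)) M^(1+p)
#'        + k_F c N - delta_M M`.
#'
#' @inheritParams reaction_fibroblast
#' @return net rate, cells/(cm^3 day).
#' @export
reaction_myofibroblast <- function(N, M, c, params) {
  check_nonneg(N = N, M = M, c = c)
  F <- N + M
  params$r_F * ((1 + params$r_F_max) * c / (params$a_c_I + c)) *
    (1 - params$kappa_F * F) * M^(1 + params$p) +
    params$k_F * c * N - params$delta_M * M
}

#' Generic MMP level
#'
#' The matrix-metalloproteinase concentration responsible for proteolysis is
#' modeled algebraically as `g = F rho / (1 + a_c_III c)`: produced by the
#' (myo)fibroblasts `F = N + M` in proportion to the collagen present, and
#' inhibited by the signaling molecule.
#'
#' @param F total (myo)fibroblast density `N + M`, cells/cm^3.
#' @param c signal concentration, g/cm^3.
#' @param rho collagen concentration, g/cm^3.
#' @param params a [scar_params()] set.
#' @return MMP level, cells g/cm^6.
#' @export
mmp_level <- function(F, c, rho, params) {
  check_nonneg(F = F, c = c, rho = rho)
  F * rho / (1 + params$a_c_III * c)
}

#' Signaling molecule net reaction rate
#'
#' Saturating net secretion by (myo)fibroblasts minus MMP-mediated
#' proteolytic breakdown:
#' `R_c = k_c (N + eta M) c/(a_c_II + c) - delta_c g(F,c,rho) c`.
#'
#' @inheritParams reaction_fibroblast
#' @param rho collagen concentration, g/cm^3.
#' @return net rate, g/(cm^3 day).
#' @export
reaction_signal <- function(N, M, c, rho, params) {
  check_nonneg(N = N, M = M, c = c, rho = rho)
  g <- mmp_level(N + M, c, rho, params)
  params$k_c * (N + params$eta * M) * c / (params$a_c_II + c) -
    params$delta_c * g * c
}

#' Collagen net reaction rate
#'
#' Secretion by (myo)fibroblasts (enhanced by the signaling molecule) minus
#' MMP-mediated degradation:
#' `R_rho = k_rho (1 + k_rho_max c/(a_c_IV + c)) (N + eta M)
#'          - delta_rho g(F,c,rho) rho`.
#'
#' @inheritParams reaction_signal
#' @return net rate, g/(cm^3 day).
#' @export
reaction_collagen <- function(N, M, c, rho, params) {
  check_nonneg(N = N, M = M, c = c, rho = rho)
  g <- mmp_level(N + M, c, rho, params)
  params$k_rho * (1 + params$k_rho_max * c / (params$a_c_IV + c)) *
    (N + params$eta * M) - params$delta_rho * g * rho
}

#' Cell flux (random motility + chemotaxis)
#'
#' `J = -D_F F grad(z) + chi_F z grad(c)` for `z` either the fibroblast or
#' the myofibroblast density. The transport equation uses `-div(J)`.
#'
#' @param z cell density (N or M), cells/cm^3.
#' @param F total density N + M, cells/cm^3.
#' @param grad_z,grad_c length-2 gradients (per cm).
#' @param params a [scar_params()] set.
#' @return length-2 flux vector, cells/(cm^2 day).
#' @export
flux_cells <- function(z, F, grad_z, grad_c, params) {
  check_nonneg(z = z, F = F)
  -params$D_F * F * grad_z + params$chi_F * z * grad_c
}

#' Signal flux (linear Fickian diffusion)
#'
#' @param grad_c length-2 gradient of the signal, g/cm^4.
#' @param params a [scar_params()] set.
#' @return length-2 flux vector, g/(cm^2 day).
#' @export
flux_signal <- function(grad_c, params) {
  -params$D_c * grad_c
}

#' Production--destruction (Patankar) splitting of the kinetics
#'
#' Writes the net rate of constituent `which` as `R = P - D * z` with
#' `P >= 0` (production, treated explicitly by the solver) and `D >= 0`
#' (destruction coefficient, treated implicitly), which makes the
#' backward-Euler update `z+ = (z + dt P) / (1 + dt D)` non-negative for any
#' step size. The logistic growth terms are non-negative as long as the
#' crowding factor `1 - kappa_F F` is; if crowding turns the growth term
#' negative it is moved into the destruction coefficient (divided by `z`)
#' so that the reconstruction identity `P - D z = R` always holds.
#'
#' @param which one of `"N"`, `"M"`, `"c"`, `"rho"`.
#' @param N,M,c,rho fields at the evaluation points (vectors).
#' @param params a [scar_params()] set.
#' @return list with vectors `P` (units of z per day) and `D` (/day).
#' @export
patankar_split <- function(which = c("N", "M", "c", "rho"),
                           N, M, c, rho, params) {
  which <- match.arg(which)
  F <- N + M
  crowd <- 1 - params$kappa_F * F
  split_growth <- function(growth, z) {
    # move a (rare) negative growth term into destruction, guarding z = 0
    P <- pmax(growth, 0)
    D_extra <- ifelse(growth < 0 & z > 0, -growth / z, 0)
    list(P = P, D = D_extra)
  }
  switch(which,
    N = {
      growth <- params$r_F * (1 + params$r_F_max * c / (params$a_c_I + c)) *
        crowd * N^(1 + params$p)
      s <- split_growth(growth, N)
      list(P = s$P, D = params$k_F * c + params$delta_N + s$D)
    },
    M = {
      growth <- params$r_F * ((1 + params$r_F_max) * c / (params$a_c_I + c)) *
        crowd * M^(1 + params$p)
      s <- split_growth(growth, M)
      list(P = s$P + params$k_F * c * N, D = params$delta_M + s$D)
    },
    c = {
      g <- F * rho / (1 + params$a_c_III * c)
      # secretion is proportional to c itself; evaluated at the known state
      # it acts as an explicit production term
      list(P = params$k_c * (N + params$eta * M) * c / (params$a_c_II + c),
           D = params$delta_c * g)
    },
    rho = {
      g <- F * rho / (1 + params$a_c_III * c)
      list(P = params$k_rho *
             (1 + params$k_rho_max * c / (params$a_c_IV + c)) *
             (N + params$eta * M),
           D = params$delta_rho * g)
    })
}
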