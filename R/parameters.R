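#' Model parameter set
#'
#' Builds the full set of model constants for the dermal wound-healing
#' simulator, defaulting to the published baseline estimates. Two constants
#' are not free: the growth-law exponent `p` and the collagen secretion rate
#' `k_rho` are necessary consequences of the unwounded equilibrium
#' (see [derive_p()] and [derive_k_rho()]) and are recomputed here from the
#' other parameters at construction time.
#'
#' Units follow the cm / day / cells / g convention used throughout the
#' package: lengths in cm, time in days, cell densities in cells/cm^3,
#' concentrations in g/cm^3, stresses in N/cm^2.
#'
#' @param ... named overrides of any parameter listed below.
#' @param check_nc warn if the recomputed `p` or `k_rho` deviates by more
#'   than 2\% from the published two-digit value (they should not, unless
#'   the inputs they derive from were overridden).
#'
#' @details Parameters (defaults in parentheses):
#' \describe{
#'   \item{E_I}{Young-modulus prefactor, N/(g cm)^(1/2) (32). The collagen
#'     dependent modulus is `E(rho) = E_I * sqrt(rho)`.}
#'   \item{nu}{Poisson ratio (0.49).}
#'   \item{xi}{myofibroblast traction per unit cell density and collagen
#'     concentration, N g/(cells cm^2) (2e-3).}
#'   \item{R}{traction saturation constant, g/cm^3 (0.3).}
#'   \item{D_F}{(myo)fibroblast cell-density-dependent motility, cm^5/(cells
#'     day) (1e-7).}
#'   \item{chi_F}{chemotaxis coefficient, cm^5/(g day) (2e-3).}
#'   \item{r_F}{fibroblast division rate, cm^(3p)/(cells^p day) (0.924).}
#'   \item{r_F_max}{division enhancement factor (2).}
#'   \item{a_c_I}{half-maximum signal level for division enhancement,
#'     g/cm^3 (1e-8).}
#'   \item{kappa_F}{crowding coefficient, cm^3/cells (1e-6).}
#'   \item{k_F}{differentiation rate, cm^3/(g day) (5.4e6).}
#'   \item{delta_N, delta_M}{fibro-/myofibroblast apoptosis rates, /day
#'     (2e-2, 6e-2; the interesting range for `delta_M` is (2--60)e-3).}
#'   \item{D_c}{signal diffusion coefficient, cm^2/day (2.9e-3).}
#'   \item{k_c}{maximum net signal secretion rate, g/(cells day) (4e-13).}
#'   \item{eta}{myofibroblast-to-fibroblast secretion ratio (2).}
#'   \item{a_c_II}{half-maximum signal level for secretion, g/cm^3 (1e-8).}
#'   \item{delta_c}{signal breakdown rate, cm^6/(cells g day) (5e-4).}
#'   \item{a_c_III}{MMP-inhibition constant, cm^3/g (2e8).}
#'   \item{k_rho_max}{collagen secretion enhancement factor (10).}
#'   \item{a_c_IV}{half-maximum signal level for collagen secretion,
#'     g/cm^3 (1e-9).}
#'   \item{delta_rho}{collagen degradation rate, cm^6/(cells g day) (6e-6).}
#'   \item{N_bar, M_bar}{equilibrium cell densities, cells/cm^3 (1e4, 0).}
#'   \item{c_bar}{equilibrium signal concentration, g/cm^3 (0).}
#'   \item{rho_bar}{equilibrium collagen concentration, g/cm^3 (0.1).}
#'   \item{N_w, rho_w}{wound initial fractions (0.2, 0.2).}
#'   \item{c_w}{initial wound signal concentration, g/cm^3 (1e-8).}
#'   \item{s1, s2}{boundary spring constants, N/g (1e6, 1e3).}
#'   \item{c_I_shape}{wound boundary steepness, cm (2).}
#'   \item{c_II_shape}{wound half-width, cm (4).}
#' }
#'
#' @return an object of class `scar_params` (a named list with the fields
#'   above plus derived `p` and `k_rho`).
#' @export
#' @examples
#' pp <- scar_params()
#' pp$p        # about -0.42
#' pp$k_rho    # 6e-8
scar_params <- function(..., check_nc = TRUE) {
  defaults <- list(
    E_I = 32, nu = 0.49,
    xi = 2e-3, R = 0.3,
    D_F = 1e-7, chi_F = 2e-3,
    r_F = 0.924, r_F_max = 2, a_c_I = 1e-8,
    kappa_F = 1e-6, k_F = 5.4e6,
    delta_N = 2e-2, delta_M = 6e-2,
    D_c = 2.9e-3, k_c = 4e-13, eta = 2, a_c_II = 1e-8,
    delta_c = 5e-4, a_c_III = 2e8,
    k_rho_max = 10, a_c_IV = 1e-9, delta_rho = 6e-6,
    N_bar = 1e4, M_bar = 0, c_bar = 0, rho_bar = 0.1,
    N_w = 0.2, rho_w = 0.2, c_w = 1e-8,
    s1 = 1e6, s2 = 1e3,
    c_I_shape = 2, c_II_shape = 4
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    defaults[names(over)] <- over
  }
  p <- defaults
  validate_params(p)
  p$p <- derive_p(p$r_F, p$kappa_F, p$delta_N, p$N_bar)
  p$k_rho <- derive_k_rho(p$delta_rho, p$rho_bar)
  if (isTRUE(check_nc)) {
    if (abs(p$p - (-0.42)) > 0.02 * 0.42)
      warning("recomputed growth exponent p = ", signif(p$p, 4),
              " deviates >2% from the published -0.42")
    if (abs(p$k_rho - 6e-8) > 0.02 * 6e-8)
      warning("recomputed k_rho = ", signif(p$k_rho, 4),
              " deviates >2% from the published 6e-8")
  }
  structure(p, class = "scar_params")
}

validate_params <- function(p) {
  nonneg <- c("E_I", "xi", "R", "D_F", "chi_F", "r_F", "r_F_max", "a_c_I",
              "kappa_F", "k_F", "delta_N", "delta_M", "D_c", "k_c", "eta",
              "a_c_II", "delta_c", "a_c_III", "k_rho_max", "a_c_IV",
              "delta_rho", "N_bar", "M_bar", "c_bar", "rho_bar", "c_w",
              "s1", "s2", "c_I_shape", "c_II_shape")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter ", nm, " must be a single finite value >= 0")
  }
  if (p$nu <= 0 || p$nu >= 0.5)
    stop("Poisson ratio nu must lie in (0, 0.5)")
  if (p$N_w < 0 || p$N_w > 1 || p$rho_w < 0 || p$rho_w > 1)
    stop("wound fractions N_w, rho_w must lie in [0, 1]")
  if (p$kappa_F * p$N_bar >= 1)
    stop("kappa_F * N_bar must be < 1 (logistic term positive at equilibrium)")
  invisible(TRUE)
}

#' @export
#' @method print scar_params
print.scar_params <- function(x, ...) {
  cat("<scar_params> dermal wound-healing model constants\n")
  nm <- setdiff(names(x), NULL)
  v <- vapply(nm, function(n) format(x[[n]], digits = 6), "")
  cat(paste0("  ", format(nm, width = 10), " = ", v, collapse = "\n"), "\n")
  invisible(x)
}

#' Growth-law exponent from the unwounded fibroblast equilibrium
#'
#' The adjusted logistic growth law for fibroblasts uses `N^(1+p)`. The
#' exponent is fixed by requiring that in unwounded dermis (no signal, no
#' myofibroblasts) division exactly balances apoptosis at the equilibrium
#' density, i.e. `r_F (1 - kappa_F N_bar) N_bar^p = delta_N`, hence
#' `p = log(delta_N / (r_F (1 - kappa_F N_bar))) / log(N_bar)`.
#'
#' @param r_F division rate, cm^(3p)/(cells^p day).
#' @param kappa_F crowding coefficient, cm^3/cells.
#' @param delta_N fibroblast apoptosis rate, /day.
#' @param N_bar equilibrium fibroblast density, cells/cm^3.
#' @return the exponent `p` (dimensionless; about -0.42 at the defaults).
#' @export
derive_p <- function(r_F, kappa_F, delta_N, N_bar) {
  if (r_F <= 0 || delta_N <= 0 || N_bar <= 0)
    stop("r_F, delta_N and N_bar must be positive")
  s <- 1 - kappa_F * N_bar
  if (s <= 0)
    stop("kappa_F * N_bar must be < 1")
  if (N_bar == 1)
    stop("N_bar = 1 leaves the exponent undetermined")
  log(delta_N / (r_F * s)) / log(N_bar)
}

#' Collagen secretion rate from the unwounded collagen equilibrium
#'
#' With no signal and no myofibroblasts the collagen kinetics reduce to
#' `k_rho N - delta_rho N rho^2`; requiring equilibrium at `rho = rho_bar`
#' for any cell density gives `k_rho = delta_rho * rho_bar^2`.
#'
#' @param delta_rho collagen degradation rate, cm^6/(cells g day).
#' @param rho_bar equilibrium collagen concentration, g/cm^3.
#' @return `k_rho` in g/(cells day) (6e-8 at the defaults).
#' @export
derive_k_rho <- function(delta_rho, rho_bar) {
  if (delta_rho <= 0 || rho_bar <= 0)
    stop("delta_rho and rho_bar must be positive")
  delta_rho * rho_bar^2
}

#' Characteristic scales for non-dimensionalization
#'
#' @param L length scale, cm. @param T time scale, day.
#' @param N cell-density scale, cells/cm^3. @param c signal scale, g/cm^3.
#' @param rho collagen scale, g/cm^3. @param stress stress scale, N/cm^2.
#' @param params parameter set used for the field-based defaults.
#' @return object of class `scar_scales`.
#' @export
scar_scales <- function(params = scar_params(),
                        L = 1, T = 1,
                        N = params$N_bar, c = params$c_w,
                        rho = params$rho_bar,
                        stress = params$E_I * sqrt(params$rho_bar)) {
  s <- list(L = L, T = T, N = N, c = c, rho = rho, stress = stress)
  if (any(!vapply(s, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, TRUE)))
    stop("all scales must be single finite positive numbers")
  structure(s, class = "scar_scales")
}

# exponent of each scale in each parameter's units; p enters through r_F
param_scale_exponents <- function(p_exp) {
  # columns: L, T, N, c, rho, stress  (value' = value * L^eL T^eT ... )
  list(
    E_I     = c(0, 0, 0, 0,  0.5, -1),
    nu      = c(0, 0, 0, 0, 0, 0),
    xi      = c(0, 0, 1, 0, -1, -1),
    R       = c(0, 0, 0, 0, -1, 0),
    D_F     = c(-2, 1, 1, 0, 0, 0),
    chi_F   = c(-2, 1, 0, 1, 0, 0),
    r_F     = c(0, 1, p_exp, 0, 0, 0),
    r_F_max = c(0, 0, 0, 0, 0, 0),
    a_c_I   = c(0, 0, 0, -1, 0, 0),
    kappa_F = c(0, 0, 1, 0, 0, 0),
    k_F     = c(0, 1, 0, 1, 0, 0),
    delta_N = c(0, 1, 0, 0, 0, 0),
    delta_M = c(0, 1, 0, 0, 0, 0),
    D_c     = c(-2, 1, 0, 0, 0, 0),
    k_c     = c(0, 1, 1, -1, 0, 0),
    eta     = c(0, 0, 0, 0, 0, 0),
    a_c_II  = c(0, 0, 0, -1, 0, 0),
    delta_c = c(0, 1, 1, 1, 0, 0),
    a_c_III = c(0, 0, 0, 1, 0, 0),
    k_rho   = c(0, 1, 1, 0, -1, 0),
    k_rho_max = c(0, 0, 0, 0, 0, 0),
    a_c_IV  = c(0, 0, 0, -1, 0, 0),
    delta_rho = c(0, 1, 1, 0, 1, 0),
    N_bar   = c(0, 0, -1, 0, 0, 0),
    M_bar   = c(0, 0, -1, 0, 0, 0),
    c_bar   = c(0, 0, 0, -1, 0, 0),
    rho_bar = c(0, 0, 0, 0, -1, 0),
    N_w     = c(0, 0, 0, 0, 0, 0),
    rho_w   = c(0, 0, 0, 0, 0, 0),
    c_w     = c(0, 0, 0, -1, 0, 0),
    s1      = c(1, 0, 0, 0, 1, -1),
    s2      = c(1, 0, 0, 0, 1, -1),
    c_I_shape  = c(-1, 0, 0, 0, 0, 0),
    c_II_shape = c(-1, 0, 0, 0, 0, 0),
    p       = c(0, 0, 0, 0, 0, 0)
  )
}

# note on signs: exponent +1 in the delta_c row for N means the dimensionless
# value is delta_c * N* (the destruction term delta_c * g * c has g ~ N rho).

scale_factor <- function(exps, scales) {
  s <- c(scales$L, scales$T, scales$N, scales$c, scales$rho, scales$stress)
  prod(s^exps)
}

#' Non-dimensionalize / re-dimensionalize a parameter set
#'
#' Rescales every constant by the powers of the characteristic scales that
#' its units demand, so that the governing equations written in the scaled
#' variables are algebraically identical to the dimensional ones. The round
#' trip `redimensionalize(nondimensionalize(p, s), s)` is the identity to
#' machine precision. Because the growth-law units of `r_F` involve the
#' exponent `p`, the (dimensionless) exponent itself is carried unchanged.
#'
#' @param params a `scar_params` object.
#' @param scales a `scar_scales` object.
#' @return a named list of scaled parameters (class `scar_params_nd`).
#' @export
nondimensionalize <- function(params, scales = scar_scales(params)) {
  stopifnot(inherits(params, "scar_params"))
  ex <- param_scale_exponents(params$p)
  out <- params
  for (nm in names(ex)) out[[nm]] <- params[[nm]] * scale_factor(ex[[nm]], scales)
  class(out) <- "scar_params_nd"
  out
}

#' @rdname nondimensionalize
#' @export
redimensionalize <- function(params, scales) {
  stopifnot(inherits(params, "scar_params_nd"))
  ex <- param_scale_exponents(params$p)
  out <- params
  for (nm in names(ex)) out[[nm]] <- params[[nm]] / scale_factor(ex[[nm]], scales)
  class(out) <- "scar_params"
  out
}

#' Read a parameter set from a YAML or JSON scenario file
#'
#' Keys are the parameter names of [scar_params()]; omitted keys keep their
#' defaults. The fully resolved set can be echoed back to a provenance file
#' with [write_params()].
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a `scar_params` object.
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- vals[!vapply(vals, is.null, TRUE)]
  vals$p <- NULL; vals$k_rho <- NULL  # derived, never read
  do.call(scar_params, vals)
}

#' @param params a `scar_params` object to write.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "scar_params"))
  yaml::write_yaml(lapply(unclass(params), unname), path)
  invisible(path)
}
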