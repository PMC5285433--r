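#' Computational domain of the dermal slice
#'
#' The model is solved on a 2D plane-strain slice of dermis through the
#' symmetry plane of a long rectangular wound: `Y` in `[-half_width,
#' half_width]` cm laterally and `Z` in `[-thickness, 0]` cm through the
#' depth. Boundary tags, counterclockwise: `B.I` bottom (interface with the
#' subcutaneous layer), `B.II` right lateral, `B.III` top (interface with
#' the epidermis), `B.IV` left lateral.
#'
#' @param half_width lateral half-extent, cm (default 15.96).
#' @param thickness dermal thickness, cm (default 0.15).
#' @return object of class `scar_domain`.
#' @export
domain_spec <- function(half_width = 15.96, thickness = 0.15) {
  stopifnot(half_width > 0, thickness > 0)
  structure(list(half_width = half_width, thickness = thickness),
            class = "scar_domain")
}

#' Wound shape specification
#'
#' @param c_I_shape steepness of the wound edge, cm (default 2).
#' @param c_II_shape wound half-width, cm (default 4; the studied range is
#'   3 to 5 cm).
#' @return object of class `scar_wound`.
#' @export
wound_spec <- function(c_I_shape = 2, c_II_shape = 4) {
  stopifnot(c_I_shape > 0, c_II_shape > 0)
  structure(list(c_I_shape = c_I_shape, c_II_shape = c_II_shape),
            class = "scar_wound")
}

#' Smoothed Heaviside ramp
#'
#' Piecewise sine ramp used to build the wound profile: 0 for
#' `x < b - a`, `(1 + sin((x - b) pi / (2a)))/2` for `|b - x| <= a`, and 1
#' for `x > b + a`. Continuous and monotone non-decreasing in `x`.
#'
#' @param x evaluation points. @param a ramp half-width (> 0). @param b
#'   ramp center.
#' @return values in \[0, 1\].
#' @export
smooth_heaviside <- function(x, a, b) {
  if (a <= 0) stop("ramp half-width a must be positive")
  out <- numeric(length(x))
  mid <- abs(b - x) <= a
  out[x > b + a] <- 1
  out[mid] <- 0.5 * (1 + sin((x[mid] - b) * pi / (2 * a)))
  out
}

#' Wound profile along the lateral coordinate
#'
#' `w(Y) = 1 - (1 - H_s(Y, c_I, c_II)) H_s(Y, c_I, -c_II)`; `w = 0` is
#' completely wounded dermis, `w = 1` unwounded tissue. Even in `Y`,
#' continuous, range `[0, 1]`.
#'
#' @param Y lateral coordinates, cm.
#' @param wound a [wound_spec()].
#' @return wound profile values in \[0, 1\].
#' @export
wound_profile <- function(Y, wound = wound_spec()) {
  a <- wound$c_I_shape; b <- wound$c_II_shape
  1 - (1 - smooth_heaviside(Y, a, b)) * smooth_heaviside(Y, a, -b)
}

#' Initial fields on a mesh
#'
#' Initializes the constituents from the wound profile `w` evaluated on the
#' reference coordinates: `N = (N_w + (1 - N_w) w) N_bar`, `M = M_bar`,
#' `c = (1 - w) c_w`, `rho = (rho_w + (1 - rho_w) w) rho_bar`. Because the
#' initial myofibroblast density is zero everywhere, the traction body
#' force vanishes and the initial displacement is identically zero.
#'
#' @param mesh a [generate_mesh()] triangulation in the reference
#'   configuration.
#' @param params a [scar_params()] set.
#' @param wound a [wound_spec()], or `NULL` for an unwounded (equilibrium)
#'   state with `w` forced to 1 everywhere.
#' @return object of class `scar_state`: time, nodal `N`, `M`, `c`, `rho`,
#'   displacement `u` (n x 2) and velocity `v` (n x 2).
#' @export
initial_state <- function(mesh, params, wound = wound_spec()) {
  Y <- mesh$X[, 1]
  w <- if (is.null(wound)) rep(1, length(Y)) else wound_profile(Y, wound)
  n <- nrow(mesh$X)
  structure(list(
    t = 0,
    N = (params$N_w + (1 - params$N_w) * w) * params$N_bar,
    M = rep(params$M_bar, n),
    c = (1 - w) * params$c_w,
    rho = (params$rho_w + (1 - params$rho_w) * w) * params$rho_bar,
    u = matrix(0, n, 2), v = matrix(0, n, 2)
  ), class = "scar_state")
}

#' Boundary condition descriptor for a boundary segment
#'
#' Returns the conditions applied on one of the tagged boundaries:
#' constituents get Dirichlet values (`N_bar`, `M_bar`, `c_bar`) on the
#' lateral boundaries `B.II`/`B.IV` and zero normal flux on `B.I`/`B.III`;
#' collagen has no boundary condition anywhere (it has no flux term). The
#' mechanical condition is spring-like: on `B.I` the normal traction is
#' `(0, -s1 rho u_z)` (a spring in z only), on `B.II`/`B.IV` it is
#' `(-s2 rho u_y, 0)` (a spring in y only), and `B.III` is traction-free.
#' Springs act on the deformed boundary with the local collagen level.
#'
#' @param tag one of `"B.I"`, `"B.II"`, `"B.III"`, `"B.IV"`.
#' @param params a [scar_params()] set.
#' @return a list describing the constituent and mechanical conditions; the
#'   `traction(rho, u_y, u_z)` element evaluates the spring traction.
#' @export
boundary_data <- function(tag, params) {
  if (!tag %in% c("B.I", "B.II", "B.III", "B.IV"))
    stop("unknown boundary tag: ", tag)
  lateral <- tag %in% c("B.II", "B.IV")
  list(
    tag = tag,
    constituents = if (lateral) {
      list(type = "dirichlet",
           values = c(N = params$N_bar, M = params$M_bar, c = params$c_bar))
    } else {
      list(type = "zero-flux")
    },
    rho = "none",
    traction = if (tag == "B.III") {
      function(rho, u_y, u_z) cbind(0 * rho, 0 * rho)
    } else if (tag == "B.I") {
      function(rho, u_y, u_z) cbind(0 * rho, -params$s1 * rho * u_z)
    } else {
      function(rho, u_y, u_z) cbind(-params$s2 * rho * u_y, 0 * rho)
    }
  )
}
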