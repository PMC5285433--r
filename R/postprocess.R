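#' Dermal thickness at the wound center
#'
#' Vertical extent between the deformed epidermal (`B.III`) and
#' subcutaneous (`B.I`) boundary curves at current `y = 0`, by linear
#' interpolation along the boundary edges. The undeformed slice returns
#' the unwounded dermal thickness (0.15 cm at the defaults).
#'
#' @param mesh a `scar_mesh` (its `cur` coordinates are used).
#' @param y lateral position at which to measure (default 0, the symmetry
#'   plane).
#' @return thickness, cm.
#' @export
thickness_at_y0 <- function(mesh, y = 0) {
  zcut <- function(tag) {
    ed <- mesh$edges[mesh$edges$tag == tag, ]
    p1 <- mesh$cur[ed$n1, , drop = FALSE]
    p2 <- mesh$cur[ed$n2, , drop = FALSE]
    lo <- pmin(p1[, 1], p2[, 1]); hi <- pmax(p1[, 1], p2[, 1])
    hit <- which(lo - 1e-12 <= y & y <= hi + 1e-12)
    if (!length(hit))
      stop("y = ", y, " lies outside the deformed ", tag, " boundary span")
    k <- hit[1]
    dy <- p2[k, 1] - p1[k, 1]
    t <- if (abs(dy) < 1e-300) 0.5 else (y - p1[k, 1]) / dy
    p1[k, 2] + t * (p2[k, 2] - p1[k, 2])
  }
  zcut("B.III") - zcut("B.I")
}

# locate the triangle containing a reference point; returns element index
# and barycentric weights
locate_point <- function(mesh, point) {
  tri <- mesh$tri; X <- mesh$X
  p1 <- X[tri[, 1], , drop = FALSE]
  p2 <- X[tri[, 2], , drop = FALSE]
  p3 <- X[tri[, 3], , drop = FALSE]
  d <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
    (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  w1 <- ((p2[, 1] - point[1]) * (p3[, 2] - point[2]) -
           (p3[, 1] - point[1]) * (p2[, 2] - point[2])) / d
  w2 <- ((p3[, 1] - point[1]) * (p1[, 2] - point[2]) -
           (p1[, 1] - point[1]) * (p3[, 2] - point[2])) / d
  w3 <- 1 - w1 - w2
  tolb <- -1e-10
  k <- which(w1 >= tolb & w2 >= tolb & w3 >= tolb)
  if (!length(k))
    stop("point (", point[1], ", ", point[2], ") lies outside the domain")
  k <- k[1]
  list(elem = k, w = pmax(c(w1[k], w2[k], w3[k]), 0))
}

#' Interpolate state fields at a material point
#'
#' The point is given in reference (Lagrangian) coordinates; because the
#' mesh convects with the tissue, barycentric interpolation in the
#' reference element automatically follows the material point through the
#' deformation.
#'
#' @param state a `scar_state`. @param mesh a `scar_mesh`.
#' @param point length-2 reference coordinates (Y, Z), cm.
#' @return one-row data frame: `t`, `N`, `M`, `c`, `rho`, `u_y`, `u_z`.
#' @export
trace_material_point <- function(state, mesh, point = c(0, -0.075)) {
  loc <- locate_point(mesh, point)
  nd <- mesh$tri[loc$elem, ]
  w <- loc$w
  ip <- function(z) sum(w * z[nd])
  data.frame(t = state$t, N = ip(state$N), M = ip(state$M),
             c = ip(state$c), rho = ip(state$rho),
             u_y = ip(state$u[, 1]), u_z = ip(state$u[, 2]))
}

#' Element-wise strain energy density field
#'
#' Evaluates `W = C1 (Ibar1 - 3) + D1 (J - 1)^2` from each element's
#' displacement gradient, reported in J/cm^3 (the natural N cm / cm^3
#' value is multiplied by 0.01). Inadmissible elements are returned as
#' `NA` with a warning listing their indices.
#'
#' @param mesh a `scar_mesh`. @param state a `scar_state` (uses `u`,
#'   `rho`).
#' @param params a [scar_params()] set.
#' @return numeric vector, one value per triangle, J/cm^3.
#' @export
strain_energy_field <- function(mesh, state, params) {
  tri <- mesh$tri
  g <- fem_geom(mesh$cur, tri)
  u <- state$u
  g11 <- u[tri[, 1], 1] * g$by[, 1] + u[tri[, 2], 1] * g$by[, 2] +
    u[tri[, 3], 1] * g$by[, 3]
  g12 <- u[tri[, 1], 1] * g$bz[, 1] + u[tri[, 2], 1] * g$bz[, 2] +
    u[tri[, 3], 1] * g$bz[, 3]
  g21 <- u[tri[, 1], 2] * g$by[, 1] + u[tri[, 2], 2] * g$by[, 2] +
    u[tri[, 3], 2] * g$by[, 3]
  g22 <- u[tri[, 1], 2] * g$bz[, 1] + u[tri[, 2], 2] * g$bz[, 2] +
    u[tri[, 3], 2] * g$bz[, 3]
  rho_e <- (state$rho[tri[, 1]] + state$rho[tri[, 2]] +
              state$rho[tri[, 3]]) / 3
  W <- energy_elems(g11, g12, g21, g22, rho_e, params) * 0.01
  if (anyNA(W))
    warning("inadmissible deformation in element(s): ",
            paste(utils::head(which(is.na(W)), 10), collapse = ", "))
  W
}

#' Scenario specification
#'
#' Bundles the quantities varied across the simulation study: the
#' myofibroblast apoptosis rate, the wound half-width, the mesh
#' resolution, the simulated duration and the output cadence.
#'
#' @param delta_M myofibroblast apoptosis rate, /day.
#' @param c_II wound half-width, cm (3 to 5).
#' @param mesh_edge target mean mesh edge length, cm.
#' @param duration simulated time, day.
#' @param trace_every material-point/thickness sampling cadence, day.
#' @param snapshot_times times (day) at which field snapshots are kept.
#' @param track_point reference coordinates of the traced material point.
#' @param seed deterministic-run seed (kept for interface stability).
#' @param params base parameter set to modify.
#' @param control solver settings.
#' @return list of class `scar_scenario`.
#' @export
scenario_spec <- function(delta_M = 6e-2, c_II = 4, mesh_edge = 0.1,
                          duration = 400, trace_every = 5,
                          snapshot_times = c(0, 25, 50, 100, 200, 400),
                          track_point = c(0, -0.075), seed = 0L,
                          params = NULL, control = solver_control()) {
  if (c_II < 3 || c_II > 5)
    warning("wound half-width c_II = ", c_II,
            " cm is outside the studied 3-5 cm range")
  structure(list(delta_M = delta_M, c_II = c_II, mesh_edge = mesh_edge,
                 duration = duration, trace_every = trace_every,
                 snapshot_times = snapshot_times,
                 track_point = track_point, seed = seed, params = params,
                 control = control),
            class = "scar_scenario")
}

#' Named scenario presets
#'
#' `high_apoptosis` and `low_apoptosis` bracket the studied apoptosis-rate
#' range at a 4 cm wound half-width; `width3`, `width4` and `width5` vary
#' the wound half-width at the low apoptosis rate.
#'
#' @param name preset name.
#' @param ... overrides passed on to [scenario_spec()].
#' @return a `scar_scenario`.
#' @export
scenario_preset <- function(name = c("high_apoptosis", "low_apoptosis",
                                     "width3", "width4", "width5"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    high_apoptosis = list(delta_M = 6e-2, c_II = 4),
    low_apoptosis = list(delta_M = 2e-3, c_II = 4),
    width3 = list(delta_M = 2e-3, c_II = 3),
    width4 = list(delta_M = 2e-3, c_II = 4),
    width5 = list(delta_M = 2e-3, c_II = 5))
  do.call(scenario_spec, utils::modifyList(base, list(...)))
}

#' Run a full wound-healing scenario
#'
#' Initializes the wound, advances the coupled solver, and collects the
#' material-point trace, the dermal thickness at `y = 0`, strain-energy
#' field snapshots and the per-step solver report.
#'
#' @param spec a [scenario_spec()] or [scenario_preset()] result.
#' @param no_wound force the wound profile to 1 everywhere (unwounded
#'   equilibrium run).
#' @param verbose print progress.
#' @return list of class `scar_run`: `trace` (data frame of the tracked
#'   quantities), `snapshots` (list of per-time field lists), `state`,
#'   `mesh`, `report`, `params`, `spec`.
#' @export
run_scenario <- function(spec = scenario_spec(), no_wound = FALSE,
                         verbose = FALSE) {
  params <- spec$params
  if (is.null(params)) params <- scar_params(delta_M = spec$delta_M,
                                             c_II_shape = spec$c_II)
  wound <- if (no_wound) NULL else
    wound_spec(params$c_I_shape, params$c_II_shape)
  mesh <- generate_mesh(domain_spec(), spec$mesh_edge, seed = spec$seed)
  state <- initial_state(mesh, params, wound)

  next_trace <- 0
  snap_times <- sort(unique(pmin(spec$snapshot_times, spec$duration)))
  snaps <- list()
  trace_rows <- list()
  t_prev <- -Inf
  snap_due <- function(t_prev, t_now)
    snap_times[snap_times > t_prev & snap_times <= t_now + 1e-9]
  rec <- function(st, ms) {
    if (st$t >= next_trace - 1e-9) {
      trace_rows[[length(trace_rows) + 1L]] <<-
        cbind(trace_material_point(st, ms, spec$track_point),
              thickness = thickness_at_y0(ms))
      next_trace <<- (floor(st$t / spec$trace_every) + 1) * spec$trace_every
    }
    for (ts in snap_due(t_prev, st$t)) {
      snaps[[sprintf("t%g", ts)]] <<- list(
        t = st$t, coords = ms$cur,
        N = st$N, M = st$M, c = st$c, rho = st$rho,
        u_mag = sqrt(rowSums(st$u^2)),
        W = strain_energy_field(ms, st, params))
    }
    t_prev <<- st$t
    NULL
  }
  rec(state, mesh)

  out <- run_simulation(mesh, state, params, spec$duration,
                        control = spec$control, record = rec,
                        verbose = verbose)
  structure(list(trace = do.call(rbind, trace_rows), snapshots = snaps,
                 state = out$state, mesh = out$mesh, report = out$report,
                 params = params, spec = spec),
            class = "scar_run")
}

#' Write the tracked time series to CSV
#' @param run a `scar_run`. @param path output file.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  utils::write.csv(run$trace, path, row.names = FALSE)
  invisible(path)
}
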