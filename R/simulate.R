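#' Simulation configuration
#'
#' Parameters of a steady-state creeping-flow run: relaxation time,
#' body-force density, flow axis/sign, and the convergence monitor.  The
#' flow is driven by a uniform body force along the flow axis, equivalent
#' to an imposed pressure gradient of the same magnitude under periodic
#' boundaries.  Convergence is declared when the relative L2 change of the
#' full velocity field per iteration (measured every `check_every`
#' iterations and divided by that interval) drops below `epsilon`.
#'
#' @param tau relaxation time (> 0.5).
#' @param force body-force density magnitude in lattice units.
#' @param flow_axis axis index (1-based) along which the force acts.
#' @param flow_sign +1 or -1.
#' @param epsilon convergence threshold on the per-iteration relative L2
#'   velocity change (default 1e-10).
#' @param check_every iterations between convergence checks (default 100).
#' @param max_iter iteration cap (default 400000).
#' @param mach_guard abort threshold on |u| in lattice units (default 0.3);
#'   exceeding it marks the run as diverged.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(tau = 1, force = 1e-5, flow_axis = 1L,
                              flow_sign = 1, epsilon = 1e-10,
                              check_every = 100L, max_iter = 400000L,
                              mach_guard = 0.3) {
  if (!(tau > 0.5)) stop("tau must exceed 0.5")
  if (!(epsilon > 0)) stop("epsilon must be positive")
  stopifnot(flow_axis %in% 1:3, flow_sign %in% c(-1, 1))
  structure(list(tau = tau, force = force, flow_axis = as.integer(flow_axis),
                 flow_sign = flow_sign, epsilon = epsilon,
                 check_every = as.integer(check_every),
                 max_iter = as.integer(max_iter), mach_guard = mach_guard),
            class = "simulation_config")
}

force_vector <- function(cfg, dimension) {
  F <- numeric(dimension)
  F[cfg$flow_axis] <- cfg$flow_sign * cfg$force
  F
}

#' Run the solver to steady state
#'
#' Iterates central-moment collision, Guo forcing, streaming and half-way
#' bounce-back until the velocity field is steady (see
#' [simulation_config()]) or the iteration cap is reached.  All outer
#' faces are periodic; solid walls anywhere (including domain-face wall
#' layers laid down by the geometry constructors) are realised by
#' bounce-back.  The run is deterministic given its inputs.
#'
#' @param geom a [pore_geometry()].
#' @param cfg a [simulation_config()].
#' @return object of class `flow_solution`: `u` (list of velocity
#'   component arrays, lattice units), `rho`, `converged`, `iterations`,
#'   `history` (tibble: iteration, el2, mean_ux), `rho_mean`, `n_fluid`,
#'   plus the `cfg` used.  Throws a condition of class
#'   `poreflow_divergence` if the fields blow up (distinct from mere
#'   non-convergence, which only warns).
#' @export
run_to_steady_state <- function(geom, cfg = simulation_config()) {
  stopifnot(inherits(geom, "pore_geometry"))
  dims <- dim(geom$solid)
  F <- force_vector(cfg, length(dims))
  res <- cpp_run_lbm(geom$solid, as.integer(dims), cfg$tau, F,
                     cfg$epsilon, cfg$check_every, cfg$max_iter,
                     cfg$mach_guard, FALSE)
  if (isTRUE(res$diverged)) {
    stop(structure(class = c("poreflow_divergence", "error", "condition"),
                   list(message = sprintf(
                     "solver diverged after %d iterations (non-finite fields or |u| > %g)",
                     res$iterations, cfg$mach_guard), call = sys.call())))
  }
  if (!isTRUE(res$converged)) {
    warning(sprintf("not converged after %d iterations (EL2 = %.3g > %.3g)",
                    res$iterations, res$el2, cfg$epsilon))
  }
  structure(list(u = res$u, rho = res$rho, converged = res$converged,
                 iterations = res$iterations, el2 = res$el2,
                 rho_mean = res$rho_mean, n_fluid = res$n_fluid,
                 history = tibble::tibble(iteration = res$history$iteration,
                                          el2 = res$history$el2,
                                          mean_ux = res$history$mean_ux),
                 cfg = cfg, dims = dims, voxel_um = geom$voxel_um),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow solution: %s grid, %d fluid nodes, %d iterations (%s)\n",
              paste(x$dims, collapse = " x "), x$n_fluid, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Relative L2 error between two fields
#'
#' `sqrt(sum((num - ref)^2) / sum(ref^2))`, flattening the inputs.
#'
#' @param numeric_field computed field (vector or array).
#' @param reference_field reference field of the same shape.
#' @return the relative L2 norm of the difference.
#' @export
l2_error <- function(numeric_field, reference_field) {
  stopifnot(length(numeric_field) == length(reference_field))
  den <- sum(reference_field^2)
  if (den == 0) stop("reference field has zero norm")
  sqrt(sum((numeric_field - reference_field)^2) / den)
}

#' Lattice-to-SI unit conversion
#'
#' Applies the mass-length-time conversion rules: lengths scale with
#' `dx`, times with `dt`, velocities with `dx/dt`, kinematic viscosities
#' with `dx^2/dt`, and permeabilities with `dx^2`.  `"permeability_darcy"`
#' additionally divides by 1 Darcy = 9.869233e-13 m^2.
#'
#' @param value quantity in lattice units.
#' @param kind one of "length", "time", "velocity",
#'   "kinematic_viscosity", "permeability", "permeability_darcy".
#' @param dx lattice spacing in metres.
#' @param dt time step in seconds (irrelevant for permeability).
#' @return the quantity in SI units (or Darcy).
#' @export
convert_units <- function(value, kind, dx, dt = 1) {
  stopifnot(dx > 0, dt > 0)
  switch(kind,
    length = value * dx,
    time = value * dt,
    velocity = value * dx / dt,
    kinematic_viscosity = value * dx^2 / dt,
    permeability = value * dx^2,
    permeability_darcy = value * dx^2 / 9.869233e-13,
    stop("unknown kind: ", kind))
}

#' Darcy permeability from a converged flow
#'
#' The superficial (Darcy) velocity is the volume average of the
#' flow-axis velocity over the *total* volume, solids counted as zero.
#' For body-force-driven periodic flow the driving pressure gradient
#' equals the body-force density, so
#' `k = rho_mean * Ud * nu / F` in lattice units; SI and Darcy values
#' follow from the voxel size.  A Reynolds number from the mean
#' interstitial speed and the declared characteristic length is attached,
#' and a warning is issued if it reaches 1 (outside the Darcy regime).
#'
#' @param sol a [run_to_steady_state()] solution.
#' @param geom the geometry the solution was computed on.
#' @param cfg the [simulation_config()] used.
#' @param char_length characteristic length in voxels for the Reynolds
#'   number (default: the smallest domain extent; the choice is recorded
#'   in the result).
#' @return object of class `permeability_result` (also a one-row tibble):
#'   `direction`, `Ud`, `k_lattice`, `k_SI`, `k_darcy`, `Re`,
#'   `char_length`, `converged`.
#' @export
darcy_permeability <- function(sol, geom, cfg = sol$cfg, char_length = NULL) {
  if (cfg$force == 0) stop("permeability is undefined for zero driving force")
  dims <- sol$dims
  axis <- cfg$flow_axis
  Ud <- cfg$flow_sign * sum(sol$u[[axis]]) / prod(dims)
  nu <- viscosity(cfg$tau)
  k_l <- sol$rho_mean * Ud * nu / cfg$force
  dx <- geom$voxel_um * 1e-6
  k_SI <- convert_units(k_l, "permeability", dx)
  k_D <- convert_units(k_l, "permeability_darcy", dx)
  if (is.null(char_length)) char_length <- min(dims)
  umag <- sqrt(Reduce(`+`, lapply(sol$u, function(a) a^2)))
  u_int <- sum(umag) / sol$n_fluid
  Re <- u_int * char_length / nu
  if (is.finite(Re) && Re >= 1) {
    warning(sprintf("Re = %.3g >= 1: outside the Darcy (creeping-flow) regime", Re))
  }
  out <- tibble::tibble(
    direction = paste0(c("x", "y", "z")[axis], if (cfg$flow_sign > 0) "+" else "-"),
    Ud = Ud, k_lattice = k_l, k_SI = k_SI, k_darcy = k_D,
    Re = Re, char_length = char_length, converged = sol$converged)
  class(out) <- c("permeability_result", class(out))
  out
}

#' Reynolds number of a converged flow
#'
#' `Re = u_int * L / nu` with the mean interstitial speed `u_int`
#' (pore-volume average of |u|) and a declared characteristic length `L`
#' in voxels.
#'
#' @param sol a [run_to_steady_state()] solution.
#' @param geom the geometry used.
#' @param cfg the configuration used.
#' @param char_length characteristic length in voxels.
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(sol, geom, cfg = sol$cfg, char_length) {
  umag <- sqrt(Reduce(`+`, lapply(sol$u, function(a) a^2)))
  (sum(umag) / sol$n_fluid) * char_length / viscosity(cfg$tau)
}

#' Write velocity and pressure fields as legacy ASCII VTK
#'
#' Structured-points file with the velocity vector, velocity magnitude and
#' pressure (`cs2 * rho`), for inspection in ParaView.
#'
#' @param sol a [run_to_steady_state()] solution.
#' @param path output file path.
#' @param voxel_um voxel size recorded as the VTK spacing.
#' @return the path, invisibly.
#' @export
write_vtk <- function(sol, path, voxel_um = sol$voxel_um) {
  dims <- sol$dims
  nd <- length(dims)
  d3 <- c(dims, rep(1L, 3 - nd))
  n <- prod(d3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "poreflow steady-state fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d3[1], d3[2], d3[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", voxel_um, voxel_um, voxel_um),
               sprintf("POINT_DATA %d", n)), con)
  u <- lapply(1:3, function(d) if (d <= nd) as.vector(sol$u[[d]]) else rep(0, n))
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.10e %.10e %.10e", u[[1]], u[[2]], u[[3]]), con)
  writeLines(c("SCALARS velocity_magnitude double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10e", sqrt(u[[1]]^2 + u[[2]]^2 + u[[3]]^2)), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.10e", as.vector(sol$rho) / 3), con)
  invisible(path)
}

#' Write the convergence history as CSV
#'
#' Columns: iteration, el2 (per-iteration relative L2 velocity change) and
#' the running permeability estimate in lattice units.
#'
#' @param sol a [run_to_steady_state()] solution.
#' @param geom the geometry used.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_convergence_csv <- function(sol, geom, path) {
  cfg <- sol$cfg
  nu <- viscosity(cfg$tau)
  phi_total <- sol$n_fluid / prod(sol$dims)
  hist <- sol$history
  # mean_ux is the fluid-average of the first velocity component; rescale to
  # the superficial average and to the configured flow axis sign
  k_run <- if (cfg$flow_axis == 1L) {
    sol$rho_mean * (hist$mean_ux * phi_total) * cfg$flow_sign * nu / cfg$force
  } else rep(NA_real_, nrow(hist))
  utils::write.csv(
    data.frame(iteration = hist$iteration, el2 = hist$el2,
               k_lattice_running = k_run),
    path, row.names = FALSE)
  invisible(path)
}
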