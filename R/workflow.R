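#' Directional permeability study
#'
#' Runs the solver once per requested direction, changing only the sign
#' and axis of the body force, and collects permeabilities and anisotropy
#' ratios.  For steady creeping flow the plus and minus runs along one
#' axis agree to a small fraction of a percent (flow reversibility), so
#' anisotropy is carried by the between-axis ratios.
#'
#' @param geom a [pore_geometry()].
#' @param cfg a [simulation_config()]; its axis/sign are overridden per run.
#' @param axes axes to probe (default all).
#' @param both_signs run both +/- along each axis (default TRUE).
#' @return object of class `directional_study`: tibble with one row per
#'   direction (columns of [darcy_permeability()]), plus attributes
#'   `ratios` (named vector of kx/ky etc.) and `partial` (TRUE when some
#'   direction failed).
#' @export
directional_permeability <- function(geom, cfg = simulation_config(),
                                     axes = seq_along(dim(geom$solid)),
                                     both_signs = TRUE) {
  signs <- if (both_signs) c(1, -1) else 1
  rows <- list()
  partial <- FALSE
  for (ax in axes) {
    for (sg in signs) {
      cfg_run <- cfg
      cfg_run$flow_axis <- as.integer(ax)
      cfg_run$flow_sign <- sg
      row <- tryCatch({
        sol <- run_to_steady_state(geom, cfg_run)
        darcy_permeability(sol, geom, cfg_run)
      }, error = function(e) {
        partial <<- TRUE
        tibble::tibble(direction = paste0(c("x", "y", "z")[ax],
                                          if (sg > 0) "+" else "-"),
                       Ud = NA_real_, k_lattice = NA_real_, k_SI = NA_real_,
                       k_darcy = NA_real_, Re = NA_real_,
                       char_length = NA_real_, converged = FALSE)
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  kmean <- vapply(axes, function(ax) {
    mean(out$k_lattice[grepl(paste0("^", c("x", "y", "z")[ax]), out$direction)],
         na.rm = TRUE)
  }, numeric(1))
  names(kmean) <- c("x", "y", "z")[axes]
  ratios <- c()
  if (length(kmean) >= 2) {
    cmb <- utils::combn(names(kmean), 2)
    ratios <- apply(cmb, 2, function(p) kmean[p[1]] / kmean[p[2]])
    names(ratios) <- apply(cmb, 2, function(p) paste0("k", p[1], "/k", p[2]))
  }
  structure(out, ratios = ratios, partial = partial,
            class = c("directional_study", class(out)))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Tie-corrected Spearman coefficient `rs` (Pearson correlation of
#' midranks) with a two-sided p-value: exact permutation enumeration for
#' `n < 10`, the usual t approximation otherwise.  Significance stars
#' follow the convention * p < 0.05, ** p < 0.01, *** p < 0.001.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return a one-row tibble: `rs`, `p_value`, `stars`, `n`, `method`.
#'   With a constant input, `rs` is undefined and returned as `NA`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rs = NA_real_, p_value = NA_real_, stars = "",
                          n = n, method = "undefined (constant input)"))
  }
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n < 10) {
    p <- cpp_spearman_perm_p(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rs = rs, p_value = p, stars = p_stars(p), n = n,
                 method = method)
}

p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Descriptor-permeability ensemble study
#'
#' Generates an ensemble of seeded synthetic foams across a grid of
#' generator parameters, computes the full structural report and the
#' flow-axis permeability for each image, and correlates every descriptor
#' with permeability by Spearman rank correlation.  Raw p-values are
#' reported with the star convention (no multiple-testing correction).
#' The run is deterministic given the seed list.
#'
#' @param param_grid a data frame whose columns override [foam_params()]
#'   arguments (e.g. `perforation_prob`, `target_porosity`); one image is
#'   generated per row.  Alternatively a list of ready `foam_params`.
#' @param cfg a [simulation_config()] for the permeability solves.
#' @param base a [foam_params()] supplying defaults for fields absent
#'   from `param_grid`.
#' @param seeds integer seeds, one per image (default `seq_len(nrow(param_grid))`).
#' @param flow_axis axis of the reported permeability.
#' @return object of class `ensemble_study`: list with `data` (one row
#'   per image: descriptors + `k_darcy` + generator parameters),
#'   `correlations` (tibble: descriptor, rs, p_value, stars) and
#'   `n_failed`.
#' @export
ensemble_study <- function(param_grid, cfg = simulation_config(),
                           base = foam_params(), seeds = NULL,
                           flow_axis = 1L) {
  if (is.data.frame(param_grid)) {
    n <- nrow(param_grid)
    if (is.null(seeds)) seeds <- seq_len(n)
    params <- lapply(seq_len(n), function(i) {
      p <- base
      for (nm in names(param_grid)) p[[nm]] <- param_grid[[nm]][i]
      p$seed <- as.integer(seeds[i])
      class(p) <- "foam_params"
      p
    })
  } else {
    params <- param_grid
    n <- length(params)
  }
  rows <- list()
  n_failed <- 0L
  for (i in seq_len(n)) {
    row <- tryCatch({
      geom <- generate_foam(params[[i]])
      rep <- pore_network_report(geom, flow_axis)
      cfg_run <- cfg
      cfg_run$flow_axis <- as.integer(flow_axis)
      sol <- suppressWarnings(run_to_steady_state(geom, cfg_run))
      perm <- darcy_permeability(sol, geom, cfg_run)
      rep$k_darcy <- perm$k_darcy
      rep$k_lattice <- perm$k_lattice
      rep$seed <- params[[i]]$seed
      rep$perforation_prob <- params[[i]]$perforation_prob
      rep$target_porosity <- params[[i]]$target_porosity
      rep
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  data <- do.call(rbind, rows)
  descriptors <- c("porosity", "effective_porosity", "main_connectivity",
                   "secondary_connectivity", "D10", "D50", "D90",
                   "mean_tortuosity", "triple_points", "quadruple_points")
  cors <- do.call(rbind, lapply(descriptors, function(d) {
    res <- spearman_correlation(data[[d]], data$k_darcy)
    tibble::tibble(descriptor = d, rs = res$rs, p_value = res$p_value,
                   stars = res$stars, n = res$n)
  }))
  structure(list(data = data, correlations = cors, n_failed = n_failed),
            class = "ensemble_study")
}

#' @export
print.ensemble_study <- function(x, ...) {
  cat(sprintf("ensemble study: %d images (%d failed)\n", nrow(x$data), x$n_failed))
  cat("Spearman correlation with permeability (raw p-values, no correction):\n")
  print(x$correlations, n = Inf)
  invisible(x)
}

#' Benchmark runner
#'
#' Builds one of the canonical verification geometries, runs the solver,
#' and compares against the analytic or reference solution:
#' * `"poiseuille"`: force-driven plane channel against the parabolic
#'   profile (relative L2 error at the node centres).
#' * `"gebart"`: hexagonal cylinder array against the closed-form
#'   transverse permeability `k/R^2`.
#' * `"fcc"`: close-packed FCC cell against the reference `k/D^2 =
#'   1.7360e-4`.
#'
#' @param name one of "poiseuille", "gebart", "fcc".
#' @param params list of benchmark parameters; see Details of each branch
#'   in the source. Unsupplied entries use the defaults.
#' @param tolerance pass/fail threshold on the reported relative error.
#' @return a one-row tibble: benchmark, measured value, reference value,
#'   relative error, pass flag, plus the geometry/solver parameters used.
#' @export
run_benchmark <- function(name = c("poiseuille", "gebart", "fcc"),
                          params = list(), tolerance = NULL) {
  name <- match.arg(name)
  if (name == "poiseuille") {
    p <- utils::modifyList(list(nx = 100L, ny = 100L, tau = 1, Re = 1), params)
    if (is.null(tolerance)) tolerance <- 3.93e-6
    H <- p$ny - 2
    nu <- viscosity(p$tau)
    umax <- p$Re * nu / H
    Fmag <- 8 * umax * nu / H^2
    geom <- make_channel(p$nx, p$ny)
    cfg <- simulation_config(tau = p$tau, force = Fmag, flow_axis = 1L)
    sol <- run_to_steady_state(geom, cfg)
    err <- poiseuille_l2_error(sol, geom, umax)
    out <- tibble::tibble(benchmark = "poiseuille", value = err,
                          reference = 0, rel_error = err,
                          pass = err <= tolerance, nx = p$nx, ny = p$ny,
                          tau = p$tau)
  } else if (name == "gebart") {
    p <- utils::modifyList(list(nx = 222L, ny = 128L, R = 30, tau = 1,
                                force = 1e-9), params)
    if (is.null(tolerance)) tolerance <- 0.05
    geom <- make_hexagonal_array(p$nx, p$ny, p$R)
    phi <- porosity(geom)
    cfg <- simulation_config(tau = p$tau, force = p$force, flow_axis = 1L)
    sol <- run_to_steady_state(geom, cfg)
    kR2 <- darcy_permeability(sol, geom, cfg)$k_lattice / p$R^2
    ref <- gebart_reference(phi)
    err <- abs(kR2 - ref) / ref
    out <- tibble::tibble(benchmark = "gebart", value = kR2, reference = ref,
                          rel_error = err, pass = err <= tolerance,
                          porosity = phi, R = p$R, tau = p$tau)
  } else {
    p <- utils::modifyList(list(L = 32L, tau = 0.6, force = 1e-7), params)
    if (is.null(tolerance)) tolerance <- 0.25
    geom <- make_fcc(p$L)
    cfg <- simulation_config(tau = p$tau, force = p$force, flow_axis = 1L)
    sol <- run_to_steady_state(geom, cfg)
    D <- p$L / sqrt(2)
    kD2 <- darcy_permeability(sol, geom, cfg)$k_lattice / D^2
    ref <- fcc_reference()
    err <- abs(kD2 - ref) / ref
    out <- tibble::tibble(benchmark = "fcc", value = kD2, reference = ref,
                          rel_error = err, pass = err <= tolerance,
                          L = p$L, tau = p$tau)
  }
  out
}

# relative L2 error of a channel solution against the analytic parabola,
# evaluated at the fluid node centres (walls half-way beyond the last
# fluid row on each side)
poiseuille_l2_error <- function(sol, geom, umax = NULL) {
  dims <- sol$dims
  ny <- dims[2]
  H <- ny - 2
  cfg <- sol$cfg
  nu <- viscosity(cfg$tau)
  if (is.null(umax)) umax <- cfg$force * H^2 / (8 * nu)
  xt <- (seq_len(H) - 0.5)                 # wall-normal position of row j
  uref <- poiseuille_reference(xt, umax, H)
  ux <- sol$u[[cfg$flow_axis]]
  prof <- colMeans(ux[, 2:(ny - 1), drop = FALSE])
  # full-field comparison: every fluid node against the parabola
  uref_grid <- matrix(uref, nrow = dims[1], ncol = H, byrow = TRUE)
  l2_error(ux[, 2:(ny - 1)], uref_grid)
}
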