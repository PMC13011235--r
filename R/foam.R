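#' Parameters of the synthetic bread-crumb foam generator
#'
#' The generator emulates the two-scale pore system of baked cellular
#' solids: large, roughly spherical gas bubbles from mixing/fermentation,
#' plus small perforations ("broken holes") through the walls between
#' neighbouring bubbles, which are what opens the structure to percolating
#' flow.  Defaults emulate a sandwich-bread crumb imaged at 18.7 um voxels
#' with porosity around 0.70 and a median bubble diameter of 0.5 mm.
#'
#' @param target_porosity pore volume fraction aimed for, in (0, 1)
#'   (default 0.70; achieved porosity is within about 0.01).
#' @param bubble_radius_mm median of the lognormal bubble-radius
#'   distribution, millimetres (default 0.25).
#' @param bubble_sigma lognormal shape (sdlog) of the radius distribution
#'   (default 0.35).
#' @param perforation_prob probability that a pair of adjacent bubbles is
#'   connected by a wall perforation, in \[0, 1\] (default 0.5).
#' @param perforation_radius_mm radius of the perforation channels,
#'   millimetres (default 0.06, i.e. about 3 voxels at 18.7 um).
#' @param elongation aspect ratio of the bubbles along the second axis
#'   (default 1.3): proofing stretches gas cells along the rise direction,
#'   which is what makes real crumb anisotropic.  1 gives spherical
#'   bubbles.
#' @param shape domain extents in voxels (default `c(400, 400)`).
#' @param voxel_um voxel size in micrometres (default 18.7).
#' @param seed integer random seed; identical seeds give identical images.
#' @return object of class `foam_params`.
#' @export
foam_params <- function(target_porosity = 0.70,
                        bubble_radius_mm = 0.25,
                        bubble_sigma = 0.35,
                        perforation_prob = 0.5,
                        perforation_radius_mm = 0.06,
                        elongation = 1.3,
                        shape = c(400, 400),
                        voxel_um = 18.7,
                        seed = 1L) {
  stopifnot(target_porosity > 0, target_porosity < 1,
            bubble_radius_mm > 0, bubble_sigma > 0,
            perforation_prob >= 0, perforation_prob <= 1,
            perforation_radius_mm > 0, elongation >= 1,
            length(shape) %in% c(2L, 3L), all(shape >= 8))
  structure(list(target_porosity = target_porosity,
                 bubble_radius_mm = bubble_radius_mm,
                 bubble_sigma = bubble_sigma,
                 perforation_prob = perforation_prob,
                 perforation_radius_mm = perforation_radius_mm,
                 elongation = elongation,
                 shape = as.integer(shape),
                 voxel_um = voxel_um,
                 seed = as.integer(seed)),
            class = "foam_params")
}

with_preserved_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# carve a periodic ellipsoidal bubble (semi-axes ax voxels) centred at ctr
carve_ball <- function(solid, ctr, ax) {
  dims <- dim(solid)
  nd <- length(dims)
  ir <- ceiling(ax)
  rng <- lapply(seq_len(nd), function(d) {
    ((round(ctr[d]) - ir[d]):(round(ctr[d]) + ir[d]) - 1L) %% dims[d] + 1L
  })
  off <- lapply(seq_len(nd), function(d) {
    x <- (round(ctr[d]) - ir[d]):(round(ctr[d]) + ir[d])
    (x - ctr[d]) / ax[d]
  })
  if (nd == 2L) {
    d2 <- outer(off[[1]]^2, off[[2]]^2, `+`)
    inside <- d2 <= 1
    solid[rng[[1]], rng[[2]]][inside] <- FALSE
  } else {
    d2 <- outer(outer(off[[1]]^2, off[[2]]^2, `+`), off[[3]]^2, `+`)
    inside <- d2 <= 1
    solid[rng[[1]], rng[[2]], rng[[3]]][inside] <- FALSE
  }
  solid
}

# carve a cylinder (2D: thick segment) of radius rp between two centres,
# using the periodic minimum-image chord; only solid voxels are affected,
# so the carved volume is exactly the wall crossing
carve_perforation <- function(solid, c1, c2, rp) {
  dims <- dim(solid)
  nd <- length(dims)
  delta <- (c2 - c1)
  delta <- delta - round(delta / dims) * dims    # minimum image
  len <- sqrt(sum(delta^2))
  if (len < 1e-9) return(solid)
  ir <- ceiling(rp) + 1L
  lo <- floor(pmin(c1, c1 + delta)) - ir
  hi <- ceiling(pmax(c1, c1 + delta)) + ir
  rng <- lapply(seq_len(nd), function(d) (lo[d]:hi[d] - 1L) %% dims[d] + 1L)
  coord <- lapply(seq_len(nd), function(d) lo[d]:hi[d])
  if (nd == 2L) {
    px <- matrix(coord[[1]], length(coord[[1]]), length(coord[[2]]))
    py <- matrix(coord[[2]], length(coord[[1]]), length(coord[[2]]), byrow = TRUE)
    rel <- list(px - c1[1], py - c1[2])
  } else {
    gx <- coord[[1]]; gy <- coord[[2]]; gz <- coord[[3]]
    px <- array(gx, c(length(gx), length(gy), length(gz)))
    py <- array(rep(gy, each = length(gx)), c(length(gx), length(gy), length(gz)))
    pz <- array(rep(gz, each = length(gx) * length(gy)),
                c(length(gx), length(gy), length(gz)))
    rel <- list(px - c1[1], py - c1[2], pz - c1[3])
  }
  tpar <- Reduce(`+`, Map(function(r, d) r * d, rel, as.list(delta))) / (len * len)
  tclamp <- pmin(pmax(tpar, 0), 1)
  d2 <- Reduce(`+`, Map(function(r, d) (r - tclamp * d)^2, rel, as.list(delta)))
  inside <- d2 <= rp * rp
  if (nd == 2L) {
    solid[rng[[1]], rng[[2]]][inside] <- FALSE
  } else {
    solid[rng[[1]], rng[[2]], rng[[3]]][inside] <- FALSE
  }
  solid
}

#' Generate a synthetic bread-crumb foam
#'
#' Seeded Boolean-bubble model: spherical (circular in 2D) bubbles with
#' lognormal radii are carved out of a solid block until the target
#' porosity is reached; every pair of adjacent bubbles is then perforated
#' with the given probability by a small channel along the centre-to-centre
#' chord, carving only the shared wall.  The domain is fully periodic,
#' matching the solver's boundary conditions.  Identical parameters
#' (including `seed`) give identical images.
#'
#' @param p a [foam_params()] object.
#' @return a [pore_geometry()] with attributes `bubbles` (matrix of
#'   centres and radii in voxels) and `perforations` (index pairs of
#'   perforated bubbles).
#' @export
generate_foam <- function(p) {
  stopifnot(inherits(p, "foam_params"))
  dims <- p$shape
  nd <- length(dims)
  vox_mm <- p$voxel_um / 1000
  r_med_vox <- p$bubble_radius_mm / vox_mm
  rp_vox <- p$perforation_radius_mm / vox_mm
  ncell <- prod(dims)
  # bubbles are ellipsoids elongated along axis 2 (the rise direction)
  shape_vec <- rep(1, nd); shape_vec[2] <- p$elongation
  e_vol <- prod(shape_vec)
  ball_vol <- function(r) e_vol * (if (nd == 2L) pi * r^2 else 4 / 3 * pi * r^3)
  target <- p$target_porosity
  build_once <- function(bubble_target) {
    with_preserved_seed(p$seed, {
      solid <- array(TRUE, dims)
      centres <- list()
      radii <- numeric(0)
      for (i in seq_len(100000L)) {
        por <- 1 - sum(solid) / ncell
        if (por >= bubble_target - 0.002) break
        r <- stats::rlnorm(1, meanlog = log(r_med_vox), sdlog = p$bubble_sigma)
        r <- max(r, 1.5)
        # cap the bubble volume by the remaining porosity budget so a
        # single large bubble cannot overshoot the target
        budget <- (bubble_target - por + 0.002) * ncell
        if (ball_vol(r) > budget) {
          r <- max(1.5, (if (nd == 2L) sqrt(budget / (pi * e_vol))
                         else (3 * budget / (4 * pi * e_vol))^(1 / 3)))
        }
        ctr <- stats::runif(nd) * dims
        solid <- carve_ball(solid, ctr, r * shape_vec)
        centres[[length(centres) + 1L]] <- ctr
        radii <- c(radii, r)
      }
      if (1 - sum(solid) / ncell < bubble_target - 0.02) {
        stop("unreachable porosity with the given bubble parameters")
      }
      cm <- do.call(rbind, centres)
      # adjacency: periodic centre distance below the radius sum plus a
      # wall allowance (vectorised over all pairs)
      perf <- matrix(integer(0), nrow = 2)
      if (nrow(cm) > 1 && p$perforation_prob > 0) {
        wall_allow <- max(4, 2 * rp_vox) * max(shape_vec)
        d2 <- matrix(0, nrow(cm), nrow(cm))
        for (d in seq_len(nd)) {
          dd <- abs(outer(cm[, d], cm[, d], `-`))
          dd <- pmin(dd, dims[d] - dd)
          d2 <- d2 + dd^2
        }
        lim <- outer(radii, radii, `+`) + wall_allow
        adj <- which(upper.tri(d2) & sqrt(d2) <= lim, arr.ind = TRUE)
        if (nrow(adj) > 0) {
          sel <- stats::runif(nrow(adj)) < p$perforation_prob
          perf <- t(adj[sel, , drop = FALSE])
          for (j in seq_len(ncol(perf))) {
            solid <- carve_perforation(solid, cm[perf[1, j], ],
                                       cm[perf[2, j], ], rp_vox)
          }
        }
      }
      geom <- pore_geometry(solid, p$voxel_um)
      attr(geom, "bubbles") <- cbind(cm, radius = radii)
      attr(geom, "perforations") <- perf
      attr(geom, "params") <- p
      geom
    })
  }
  # the perforations add pore volume that depends on the realised bubble
  # pattern; correct the bubble-phase target until the final porosity is
  # within tolerance (deterministic: each pass restarts from the seed)
  bubble_target <- target
  geom <- build_once(bubble_target)
  for (pass in 1:6) {
    overshoot <- porosity(geom) - target
    if (abs(overshoot) <= 0.006) break
    bubble_target <- bubble_target - 0.8 * overshoot
    if (bubble_target <= 0.02) stop("unreachable porosity after perforation correction")
    geom <- build_once(bubble_target)
  }
  geom
}
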