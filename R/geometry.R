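#' Binary pore geometry
#'
#' The shared container for the solver and the structural metrics: a binary
#' solid mask (TRUE = solid, FALSE = pore) on a rectangular voxel grid with
#' a physical voxel size.
#'
#' @param solid logical array (2D or 3D), TRUE marks solid voxels.
#' @param voxel_um physical voxel edge length in micrometres.
#' @return object of class `pore_geometry`.
#' @export
pore_geometry <- function(solid, voxel_um = 18.7) {
  stopifnot(is.logical(solid), length(dim(solid)) %in% c(2L, 3L))
  if (!any(!solid)) stop("geometry must contain at least one fluid voxel")
  structure(list(solid = solid, voxel_um = as.numeric(voxel_um),
                 dimension = length(dim(solid))),
            class = "pore_geometry")
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf("pore geometry: %s voxels at %.3g um, porosity %.4f\n",
              paste(dim(x$solid), collapse = " x "), x$voxel_um,
              mean(!x$solid)))
  invisible(x)
}

#' Plane channel geometry
#'
#' A straight channel open along the first (flow) axis with solid side
#' walls one voxel thick on the second axis.  In 3D the third axis is left
#' periodic (a parallel-plate slit).  `ny` voxels across give `ny - 2`
#' fluid rows and porosity `(ny - 2) / ny`.
#'
#' @param nx extent along the flow axis.
#' @param ny extent across the channel (walls at both ends of this axis).
#' @param nz optional third extent (slit depth).
#' @param voxel_um voxel size in micrometres.
#' @return a [pore_geometry()].
#' @export
make_channel <- function(nx, ny, nz = NULL, voxel_um = 18.7) {
  if (nx < 3 || ny < 3) stop("degenerate channel: need nx, ny >= 3")
  dims <- if (is.null(nz)) c(nx, ny) else c(nx, ny, nz)
  solid <- array(FALSE, dims)
  if (is.null(nz)) {
    solid[, c(1, ny)] <- TRUE
  } else {
    solid[, c(1, ny), ] <- TRUE
  }
  pore_geometry(solid, voxel_um)
}

#' Hexagonal cylinder array
#'
#' Periodic unit cell of a hexagonal arrangement of circular solid
#' particles: quarter disks at the four corners plus a full disk at the
#' centre.  With the default aspect ratio `nx / ny` close to sqrt(3) the
#' periodic tiling is the regular hexagonal packing used in Gebart's
#' transverse-flow permeability analysis (see [gebart_reference()]).  The
#' cell holds two whole disks of solid, so the nominal porosity is
#' `1 - 2 * pi * R^2 / (nx * ny)`; the returned mask porosity differs only
#' by voxelisation error.
#'
#' @param nx,ny cell extents in voxels (default 440 x 254).
#' @param R particle radius in voxels.
#' @param voxel_um voxel size in micrometres.
#' @return a [pore_geometry()].
#' @export
make_hexagonal_array <- function(nx = 440, ny = 254, R, voxel_um = 18.7) {
  if (R <= 0) stop("R must be positive")
  if (2 * R > min(nx, ny)) stop("disks overlap the cell inconsistently: 2R exceeds cell extent")
  xs <- (seq_len(nx) - 0.5)
  ys <- (seq_len(ny) - 0.5)
  px <- matrix(xs, nx, ny)
  py <- matrix(ys, nx, ny, byrow = TRUE)
  centres <- rbind(c(0, 0), c(nx / 2, ny / 2))
  solid <- matrix(FALSE, nx, ny)
  for (i in seq_len(nrow(centres))) {
    dx <- abs(px - centres[i, 1]); dx <- pmin(dx, nx - dx)
    dy <- abs(py - centres[i, 2]); dy <- pmin(dy, ny - dy)
    solid <- solid | (dx * dx + dy * dy <= R * R)
  }
  pore_geometry(solid, voxel_um)
}

#' Face-centred-cubic sphere packing
#'
#' Voxelised periodic unit cell of the close-packed FCC arrangement:
#' spheres at the cube corners and face centres, radius `sqrt(2)/4` of the
#' cell side so that neighbouring spheres touch along the face diagonals.
#' The analytic void fraction is `1 - pi / (3 * sqrt(2)) = 0.25952`; the
#' voxel porosity converges to it as `L` grows (node-centre-in-solid rule,
#' no anti-aliasing).
#'
#' @param L cell side in voxels (>= 16, even).
#' @param voxel_um voxel size in micrometres.
#' @return a [pore_geometry()].
#' @seealso [fcc_porosity()], [fcc_reference()] for the reference
#'   dimensionless permeability.
#' @export
make_fcc <- function(L, voxel_um = 18.7) {
  if (L < 16 || L %% 2 != 0) stop("L must be an even integer >= 16")
  pore_geometry(cpp_make_fcc(as.integer(L)), voxel_um)
}

#' Analytic FCC void fraction
#'
#' Void fraction of the close-packed FCC sphere packing:
#' `1 - pi / (3 * sqrt(2))`.
#'
#' @return the void fraction (about 0.25952).
#' @export
fcc_porosity <- function() 1 - pi / (3 * sqrt(2))

#' Voxel coarsening
#'
#' Block-averages the mask by an integer factor: a coarse cell containing
#' strictly more than 50% solid voxels becomes solid, otherwise fluid
#' (exact ties are fluid).  The voxel size is multiplied by the factor.
#' Dimensions not divisible by the factor are padded by edge replication
#' with a warning.
#'
#' @param geom a [pore_geometry()].
#' @param factor integer block size (>= 2).
#' @return the coarsened [pore_geometry()].
#' @export
coarsen <- function(geom, factor) {
  factor <- as.integer(factor)
  if (factor < 2) stop("factor must be >= 2")
  solid <- geom$solid
  dims <- dim(solid)
  pad <- (factor - dims %% factor) %% factor
  if (any(pad > 0)) {
    warning("dimensions not divisible by factor; padding by edge replication")
    for (d in which(pad > 0)) {
      idx <- lapply(dims, seq_len)
      idx[[d]] <- c(seq_len(dims[d]), rep(dims[d], pad[d]))
      solid <- do.call(`[`, c(list(solid), idx, list(drop = FALSE)))
      dims <- dim(solid)
    }
  }
  nd <- dims %/% factor
  dimn <- length(dims)
  if (dimn == 2L) {
    arr <- array(solid, c(factor, nd[1], factor, nd[2]))
    frac <- apply(arr, c(2, 4), mean)
  } else {
    arr <- array(solid, c(factor, nd[1], factor, nd[2], factor, nd[3]))
    frac <- apply(arr, c(2, 4, 6), mean)
  }
  pore_geometry(frac > 0.5, geom$voxel_um * factor)
}

#' Centred sub-volume extraction
#'
#' Crops a centred square/cubic (or rectangular) sub-volume, as used for
#' representative-elementary-volume analysis.  Nested crops share their
#' centre.
#'
#' @param geom a [pore_geometry()].
#' @param size scalar or per-axis extents of the crop.
#' @return the cropped [pore_geometry()].
#' @export
extract_rev <- function(geom, size) {
  dims <- dim(geom$solid)
  size <- rep(as.integer(size), length.out = length(dims))
  if (any(size > dims)) stop("crop size exceeds domain extent")
  if (any(size < 1)) stop("crop size must be positive")
  start <- pmax(1L, (dims - size) %/% 2L + 1L)
  idx <- lapply(seq_along(dims), function(d) seq(start[d], start[d] + size[d] - 1L))
  solid <- do.call(`[`, c(list(geom$solid), idx, list(drop = FALSE)))
  pore_geometry(solid, geom$voxel_um)
}

#' Save / load a geometry as a TIFF stack
#'
#' 8-bit TIFF with 255 = pore and 0 = solid (multi-directory stack for 3D),
#' plus a sidecar `<path>.meta` text file recording the voxel size.
#' Reading applies the threshold `> 127` is pore.
#'
#' @param geom a [pore_geometry()].
#' @param path output TIFF path.
#' @return `write_geometry_tiff` the path, invisibly;
#'   `read_geometry_tiff` a [pore_geometry()].
#' @export
write_geometry_tiff <- function(geom, path) {
  solid <- geom$solid
  if (geom$dimension == 2L) {
    img <- t(1 - solid * 1)  # rows = y for conventional viewing
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else {
    slices <- lapply(seq_len(dim(solid)[3]),
                     function(z) t(1 - solid[, , z] * 1))
    tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  }
  writeLines(c(sprintf("voxel_um: %.10g", geom$voxel_um),
               sprintf("dims: %s", paste(dim(solid), collapse = " "))),
             paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_geometry_tiff
#' @param voxel_um voxel size override; if missing, read from the sidecar.
#' @export
read_geometry_tiff <- function(path, voxel_um = NULL) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (is.null(voxel_um)) {
    meta <- paste0(path, ".meta")
    voxel_um <- if (file.exists(meta)) {
      as.numeric(sub("voxel_um: *", "", grep("voxel_um", readLines(meta), value = TRUE)[1]))
    } else 18.7
  }
  to_solid <- function(m) t(m) <= (127 / 255)
  if (length(img) == 1L) {
    solid <- to_solid(img[[1]])
  } else {
    slices <- lapply(img, to_solid)
    solid <- array(FALSE, c(dim(slices[[1]]), length(slices)))
    for (z in seq_along(slices)) solid[, , z] <- slices[[z]]
  }
  pore_geometry(solid, voxel_um)
}
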