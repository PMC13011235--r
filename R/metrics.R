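#' Porosity
#'
#' Fraction of pore (fluid) voxels in the image.
#'
#' @param geom a [pore_geometry()].
#' @return porosity in \[0, 1\].
#' @export
porosity <- function(geom) mean(!geom$solid)

#' Pore component labelling
#'
#' Face-connected (4-neighbour in 2D, 6-neighbour in 3D) connected
#' components of the pore phase.  Face connectivity is the flow-relevant
#' choice: bounce-back walls block transport through diagonal-only
#' contacts.  Labels are deterministic: 1 is the largest component,
#' ties broken by the smallest linear voxel index.
#'
#' @param geom a [pore_geometry()].
#' @return integer array of labels (0 = solid) with attribute `sizes`
#'   (voxel count per label).
#' @export
label_components <- function(geom) {
  lab <- cpp_label_components(geom$solid, as.integer(dim(geom$solid)))
  n <- max(lab)
  sizes <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer(0)
  attr(lab, "sizes") <- sizes
  lab
}

#' Directional connectivity flags
#'
#' Binary indicators of a percolating pore path: `main = 1` when some
#' component touches both faces along the flow axis, `secondary` is the
#' same test along a perpendicular axis (the next axis, cyclically).
#'
#' @param labels label array from [label_components()].
#' @param flow_axis axis index (1-based).
#' @return named integer vector `c(main = 0/1, secondary = 0/1)`.
#' @export
connectivity_flags <- function(labels, flow_axis = 1L) {
  nd <- length(dim(labels))
  sec_axis <- (flow_axis %% nd) + 1L
  c(main = spans_axis(labels, flow_axis),
    secondary = spans_axis(labels, sec_axis))
}

face_labels <- function(labels, axis, which_face) {
  dims <- dim(labels)
  idx <- lapply(dims, seq_len)
  idx[[axis]] <- if (which_face == 1L) 1L else dims[axis]
  face <- do.call(`[`, c(list(labels), idx, list(drop = FALSE)))
  unique(face[face > 0])
}

spans_axis <- function(labels, axis) {
  a <- face_labels(labels, axis, 1L)
  b <- face_labels(labels, axis, 2L)
  as.integer(length(intersect(a, b)) > 0)
}

#' Effective porosity
#'
#' Volume fraction of pore voxels belonging to spanning components, i.e.
#' components that touch two opposite faces along at least one axis.
#' Isolated closed pores raise the total porosity but not this quantity,
#' which is the flow-relevant pore fraction.  Always `<= porosity`.
#'
#' @param geom a [pore_geometry()].
#' @return effective porosity in \[0, 1\].
#' @export
effective_porosity <- function(geom) {
  labels <- label_components(geom)
  nd <- length(dim(labels))
  spanning <- integer(0)
  for (axis in seq_len(nd)) {
    a <- face_labels(labels, axis, 1L)
    b <- face_labels(labels, axis, 2L)
    spanning <- union(spanning, intersect(a, b))
  }
  if (length(spanning) == 0) return(0)
  sum(labels %in% spanning) / length(labels)
}

#' Local thickness map
#'
#' Per-pore-voxel diameter of the largest sphere (disk in 2D) that lies
#' entirely in the pore space and covers the voxel
#' (Hildebrand-Ruegsegger construction: exact Euclidean distance
#' transform followed by sphere coverage).  The phase boundary is taken
#' half-way between voxel centres.
#'
#' @param geom a [pore_geometry()].
#' @param units "mm" (default) or "voxel".
#' @return numeric array of diameters; solid voxels are `NA`.
#' @export
local_thickness <- function(geom, units = c("mm", "voxel")) {
  units <- match.arg(units)
  th <- cpp_local_thickness(geom$solid, as.integer(dim(geom$solid)))
  th[geom$solid] <- NA_real_
  if (units == "mm") th <- th * geom$voxel_um / 1000
  th
}

#' Pore-size distribution quantiles
#'
#' Volume-weighted quantiles of the local-thickness map: D10, D50 and D90
#' are the diameters below which 10%, 50% and 90% of the pore volume
#' lies (midpoint-interpolated empirical quantiles).
#'
#' @param thickness a [local_thickness()] map (or any numeric vector of
#'   per-voxel thickness values; `NA`s are dropped).
#' @return named vector `c(D10, D50, D90)` in the map's units, with the
#'   histogram (`hist` attribute: tibble of breaks and volume fractions).
#' @export
psd_quantiles <- function(thickness) {
  v <- as.numeric(thickness)
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("empty pore space: no thickness values")
  q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE, type = 5)
  names(q) <- c("D10", "D50", "D90")
  h <- graphics::hist(v, breaks = "FD", plot = FALSE)
  attr(q, "hist") <- tibble::tibble(mid = h$mids,
                                    volume_fraction = h$counts / sum(h$counts))
  q
}

#' Skeletonize the pore space
#'
#' Topology-preserving medial-axis thinning of the pore phase, followed by
#' graph extraction: junction voxels (more than two full-connectivity
#' neighbours) are clustered into junction nodes, chains of degree-2
#' voxels become branches with an arc length accumulated from Euclidean
#' step weights (1, sqrt(2), sqrt(3)) and a chord equal to the straight
#' endpoint distance.
#'
#' @param geom a [pore_geometry()].
#' @return object of class `skeleton_graph`: list with `skeleton`
#'   (logical array), `branches` (tibble: arc, chord, tortuosity, valid,
#'   loop), `junctions` (tibble: id, degree), `n_endpoints`.
#' @export
skeletonize <- function(geom) {
  dims <- dim(geom$solid)
  nd <- length(dims)
  skel <- cpp_skeletonize(geom$solid, as.integer(dims))
  vox <- which(skel)
  if (length(vox) == 0) {
    return(structure(list(skeleton = skel,
                          branches = empty_branches(),
                          junctions = tibble::tibble(id = integer(0), degree = integer(0)),
                          n_endpoints = 0L),
                     class = "skeleton_graph"))
  }
  coords <- arrayInd(vox, dims)
  key <- as.integer(vox)
  pos <- match(seq_len(prod(dims)), key)    # grid index -> skeleton index
  # full-connectivity neighbour offsets
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nvox <- length(vox)
  nbr <- vector("list", nvox)
  for (i in seq_len(nvox)) {
    p <- coords[i, ]
    nb <- integer(0)
    for (j in seq_len(nrow(offs))) {
      q <- p + offs[j, ]
      if (any(q < 1) || any(q > dims)) next
      g <- q[1] + (q[2] - 1) * dims[1] +
        if (nd == 3) (q[3] - 1) * dims[1] * dims[2] else 0
      s <- pos[g]
      if (!is.na(s)) nb <- c(nb, s)
    }
    nbr[[i]] <- nb
  }
  deg <- lengths(nbr)
  is_node <- deg != 2L
  # cluster adjacent node voxels into junction/end nodes
  node_id <- integer(nvox)
  nid <- 0L
  for (i in which(is_node)) {
    if (node_id[i] > 0) next
    nid <- nid + 1L
    stack <- i
    node_id[i] <- nid
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in nbr[[v]]) {
        if (is_node[w] && node_id[w] == 0) {
          node_id[w] <- nid
          stack <- c(stack, w)
        }
      }
    }
  }
  step_len <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))
  chord_len <- function(a, b) sqrt(sum((coords[a, ] - coords[b, ])^2))
  branches <- list()
  visited_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  add_branch <- function(arc, from, to, loop) {
    chord <- chord_len(from, to)
    branches[[length(branches) + 1L]] <<- c(arc = arc, chord = chord,
                                            from = node_id[from], to = node_id[to],
                                            loop = as.integer(loop))
  }
  # trace from every node voxel into each non-node neighbour chain,
  # and record direct node-node adjacencies
  for (i in which(is_node)) {
    for (w in nbr[[i]]) {
      if (is_node[w]) {
        if (node_id[w] == node_id[i]) next
        k <- edge_key(i, w)
        if (!is.null(visited_edge[[k]])) next
        visited_edge[[k]] <- TRUE
        add_branch(step_len(i, w), i, w, FALSE)
      } else {
        k <- edge_key(i, w)
        if (!is.null(visited_edge[[k]])) next
        visited_edge[[k]] <- TRUE
        arc <- step_len(i, w)
        prev <- i; cur <- w
        repeat {
          nxt <- setdiff(nbr[[cur]], prev)
          if (length(nxt) == 0) { add_branch(arc, i, cur, FALSE); break }
          nxt <- nxt[1]
          arc <- arc + step_len(cur, nxt)
          if (is_node[nxt]) {
            visited_edge[[edge_key(nxt, cur)]] <- TRUE
            add_branch(arc, i, nxt, FALSE)
            break
          }
          prev <- cur; cur <- nxt
        }
      }
    }
  }
  # pure cycles (all voxels degree 2) remain untraced; find them by marking
  # chain voxels reachable from node voxels
  reach <- is_node
  for (i in which(is_node)) {
    for (w in nbr[[i]]) {
      if (is_node[w]) next
      prev <- i; cur <- w
      while (!is.na(cur) && !reach[cur]) {
        reach[cur] <- TRUE
        nxt <- setdiff(nbr[[cur]], prev)
        if (length(nxt) == 0) break
        prev <- cur; cur <- nxt[1]
        if (is_node[cur]) break
      }
    }
  }
  for (i in which(!reach)) {
    if (reach[i]) next
    # trace the cycle
    arc <- 0
    prev <- i; cur <- nbr[[i]][1]
    reach[i] <- TRUE
    arc <- arc + step_len(i, cur)
    while (cur != i) {
      reach[cur] <- TRUE
      nxt <- setdiff(nbr[[cur]], prev)[1]
      arc <- arc + step_len(cur, nxt)
      prev <- cur; cur <- nxt
    }
    nid <- nid + 1L
    node_id[i] <- nid
    branches[[length(branches) + 1L]] <- c(arc = arc, chord = 0,
                                           from = nid, to = nid, loop = 1L)
  }
  br <- if (length(branches)) {
    m <- do.call(rbind, branches)
    tibble::tibble(arc = unname(m[, "arc"]), chord = unname(m[, "chord"]),
                   from = as.integer(m[, "from"]), to = as.integer(m[, "to"]),
                   loop = unname(m[, "loop"]) == 1L)
  } else empty_branches()
  br$tortuosity <- ifelse(br$chord > 0, br$arc / br$chord, NA_real_)
  # valid branches: distinct endpoints and a chord longer than one voxel
  br$valid <- !br$loop & br$chord > 1 & br$arc > 0
  # junction table: degree = number of incident branches
  ids <- sort(unique(node_id[node_id > 0]))
  degree <- vapply(ids, function(id) {
    sum(br$from == id) + sum(br$to == id) - sum(br$from == id & br$to == id & !br$loop)
  }, integer(1))
  # count endpoints: node clusters of a single voxel with skeleton degree <= 1
  n_end <- sum(vapply(ids, function(id) {
    vs <- which(node_id == id)
    length(vs) == 1L && deg[vs] <= 1L
  }, logical(1)))
  structure(list(skeleton = skel,
                 branches = br,
                 junctions = tibble::tibble(id = ids, degree = degree),
                 n_endpoints = n_end),
            class = "skeleton_graph")
}

empty_branches <- function() {
  tibble::tibble(arc = numeric(0), chord = numeric(0), from = integer(0),
                 to = integer(0), loop = logical(0),
                 tortuosity = numeric(0), valid = logical(0))
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton graph: %d branches (%d valid), %d junction/end nodes\n",
              nrow(x$branches), sum(x$branches$valid), nrow(x$junctions)))
  invisible(x)
}

#' Branch and mean tortuosity
#'
#' Tortuosity of one branch is its arc length (Euclidean voxel steps)
#' divided by the straight-line endpoint distance; always >= 1.  The mean
#' is taken unweighted over valid branches (distinct endpoints, chord
#' longer than one voxel); loops are excluded and counted separately.
#'
#' @param branch one row of the `branches` tibble of a
#'   [skeletonize()] result (or any list with `arc` and `chord`).
#' @return the branch tortuosity.
#' @export
branch_tortuosity <- function(branch) {
  if (is.null(branch$chord) || branch$chord <= 0) {
    stop("loop branch (coincident endpoints) has no defined tortuosity")
  }
  branch$arc / branch$chord
}

#' @rdname branch_tortuosity
#' @param graph a [skeletonize()] result.
#' @return `mean_tortuosity`: the unweighted mean over valid branches
#'   (NA when there are none).
#' @export
mean_tortuosity <- function(graph) {
  v <- graph$branches$tortuosity[graph$branches$valid]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Junction counts
#'
#' Numbers of junction nodes with exactly three (triple points) and
#' exactly four (quadruple points) incident branches.
#'
#' @param graph a [skeletonize()] result.
#' @return named integer vector `c(triple, quadruple)`.
#' @export
junction_counts <- function(graph) {
  d <- graph$junctions$degree
  c(triple = sum(d == 3L), quadruple = sum(d == 4L))
}

#' Full structural report of one image
#'
#' All structural descriptors of a binary pore image in one row:
#' porosity, effective porosity, component count, connectivity flags,
#' pore-size quantiles (mm), mean tortuosity and junction counts.
#'
#' @param geom a [pore_geometry()].
#' @param flow_axis axis for the connectivity flags (default 1).
#' @return a one-row tibble of class `pore_network_report`.
#' @export
pore_network_report <- function(geom, flow_axis = 1L) {
  labels <- label_components(geom)
  conn <- connectivity_flags(labels, flow_axis)
  th <- local_thickness(geom)
  q <- psd_quantiles(th)
  g <- skeletonize(geom)
  jc <- junction_counts(g)
  out <- tibble::tibble(
    porosity = porosity(geom),
    effective_porosity = effective_porosity(geom),
    n_components = max(labels),
    main_connectivity = conn[["main"]],
    secondary_connectivity = conn[["secondary"]],
    D10 = q[["D10"]], D50 = q[["D50"]], D90 = q[["D90"]],
    mean_tortuosity = mean_tortuosity(g),
    n_branches = nrow(g$branches),
    triple_points = jc[["triple"]],
    quadruple_points = jc[["quadruple"]])
  class(out) <- c("pore_network_report", class(out))
  out
}

#' Representative-elementary-volume analysis
#'
#' Computes porosity and directional permeability on centred sub-volumes
#' of increasing size, the standard way of locating the size beyond which
#' descriptors stabilise.  Sub-volumes share their centre; the last size
#' may equal the full extent.
#'
#' @param geom a [pore_geometry()].
#' @param sizes increasing vector of crop extents (voxels).
#' @param cfg a [simulation_config()] used for every solve.
#' @param axes axes along which to measure permeability (default: all).
#' @param rel_tol relative-change tolerance used to flag convergence of
#'   the descriptor curves (default 0.05).
#' @return a tibble: size, porosity, one `k_darcy_<axis>` column per axis,
#'   and `stable` (TRUE from the first size where all descriptors change
#'   by less than `rel_tol` relative to the previous size).
#' @export
rev_analysis <- function(geom, sizes, cfg = simulation_config(),
                         axes = seq_along(dim(geom$solid)), rel_tol = 0.05) {
  stopifnot(all(diff(sizes) > 0))
  rows <- lapply(sizes, function(s) {
    sub <- extract_rev(geom, s)
    row <- tibble::tibble(size = s, porosity = porosity(sub))
    for (ax in axes) {
      cfg_ax <- cfg
      cfg_ax$flow_axis <- as.integer(ax)
      k <- tryCatch({
        sol <- run_to_steady_state(sub, cfg_ax)
        darcy_permeability(sol, sub, cfg_ax)$k_darcy
      }, poreflow_divergence = function(e) NA_real_)
      row[[paste0("k_darcy_", c("x", "y", "z")[ax])]] <- k
    }
    row
  })
  out <- do.call(rbind, rows)
  vals <- as.matrix(out[, -1])
  stable <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    rel <- abs(vals[i, ] - vals[i - 1, ]) / pmax(abs(vals[i - 1, ]), 1e-300)
    stable[i] <- all(rel < rel_tol, na.rm = TRUE)
  }
  out$stable <- stable
  out
}
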