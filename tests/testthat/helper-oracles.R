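# Independent oracles used across the suite.  These deliberately avoid the
# package's own computational paths: transforms are dense matrix solves,
# labelling is a plain flood fill, local thickness is exhaustive sphere
# enumeration.

# dense central-moment transform matrix: row alpha = monomial exponents,
# column i = direction; entry prod((c_i - u)^e)
oracle_cm_matrix <- function(u, stencil) {
  exps <- as.matrix(expand.grid(rep(list(0:2), stencil$dimension)))
  # match the monomial ordering: last axis fastest
  exps <- exps[, rev(seq_len(ncol(exps))), drop = FALSE]
  ord <- do.call(order, as.data.frame(exps))
  exps <- exps[ord, , drop = FALSE]
  T <- matrix(0, stencil$Q, stencil$Q)
  for (a in seq_len(stencil$Q)) {
    for (i in seq_len(stencil$Q)) {
      T[a, i] <- prod((stencil$velocities[i, ] - u)^exps[a, ])
    }
  }
  T
}

# direct BGK collision + Guo forcing, straight from the textbook formulas
oracle_bgk_step <- function(f, tau, F, stencil) {
  rho <- sum(f)
  u <- (colSums(stencil$velocities * f) + F / 2) / rho
  feq <- equilibrium(rho, u, stencil)
  cs2 <- stencil$cs2
  guo <- vapply(seq_len(stencil$Q), function(i) {
    ci <- stencil$velocities[i, ]
    w <- stencil$weights[i]
    w * sum(((ci - u) / cs2 + sum(ci * u) * ci / cs2^2) * F)
  }, numeric(1))
  f + (feq - f) / tau + (1 - 1 / (2 * tau)) * guo
}

# plain recursive-free flood fill component count (face connectivity)
oracle_flood_fill <- function(solid) {
  dims <- dim(solid)
  nd <- length(dims)
  lab <- array(0L, dims)
  nextlab <- 0L
  offs <- diag(nd)
  offs <- rbind(offs, -offs)
  idx_all <- which(!solid)
  for (start in idx_all) {
    if (lab[start] > 0) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      p <- arrayInd(v, dims)
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > dims)) next
        g <- q[1] + (q[2] - 1) * dims[1] +
          if (nd == 3) (q[3] - 1) * dims[1] * dims[2] else 0
        if (!solid[g] && lab[g] == 0) {
          lab[g] <- nextlab
          queue <- c(queue, g)
        }
      }
    }
  }
  lab
}

# exhaustive local thickness: every pore voxel is a candidate sphere centre
# with radius dist-to-nearest-solid-centre - 1/2; thickness of v is the
# largest diameter over candidate spheres covering v
oracle_local_thickness <- function(solid) {
  dims <- dim(solid)
  nd <- length(dims)
  pores <- which(!solid)
  solids <- which(solid)
  coords <- arrayInd(pores, dims)
  th <- rep(0, length(pores))
  if (length(solids) == 0) {
    return(array(max(dims), dims))
  }
  scoords <- arrayInd(solids, dims)
  r <- vapply(seq_along(pores), function(i) {
    d2 <- rowSums((t(t(scoords) - coords[i, ]))^2)
    sqrt(min(d2)) - 0.5
  }, numeric(1))
  r[r < 0] <- 0
  for (i in seq_along(pores)) {      # candidate centre
    for (j in seq_along(pores)) {    # covered voxel
      d <- sqrt(sum((coords[j, ] - coords[i, ])^2))
      if (d <= r[i]) th[j] <- max(th[j], 2 * r[i])
    }
  }
  out <- array(NA_real_, dims)
  out[pores] <- th
  out
}

# one full R-composed solver step using the package's node-level operations,
# for parity with the fused engine
r_reference_step <- function(field, tau, F) {
  st <- field$stencil
  dims <- utils::head(dim(field$f), -1)
  rv <- relaxation_frequencies(tau, st)
  fluid_idx <- which(!field$solid)
  nQ <- st$Q
  fmat <- matrix(field$f, ncol = nQ)
  for (g in fluid_idx) {
    f <- fmat[g, ]
    rho <- sum(f)
    u <- (colSums(st$velocities * f) + F / 2) / rho
    fpost <- collide(f, u, rv)
    fpost <- apply_force(fpost, F, rho, u, rv)$f
    fmat[g, ] <- fpost
  }
  field$f <- array(fmat, dim = c(dims, nQ))
  field <- halfway_bounce_back(field)
  stream(field)
}

# small deterministic random geometry helpers
random_mask <- function(dims, p_solid, seed) {
  set.seed(seed)
  arr <- array(stats::runif(prod(dims)) < p_solid, dims)
  if (all(arr)) arr[1] <- FALSE
  arr
}

small_foam_params <- function(seed, perforation_prob = 0.5,
                              target_porosity = 0.70, shape = c(64, 64)) {
  foam_params(target_porosity = target_porosity,
              bubble_radius_mm = 0.10, bubble_sigma = 0.30,
              perforation_prob = perforation_prob,
              perforation_radius_mm = 0.04,
              shape = shape, voxel_um = 18.7, seed = seed)
}
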