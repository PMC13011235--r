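#' Equilibrium distribution
#'
#' Third-order truncated Maxwellian equilibrium populations for a node with
#' density `rho` and velocity `u`.  Includes the cubic velocity terms
#' \eqn{(c_i u)^3 / (6 c_s^6) - (c_i u) u^2 / (2 c_s^4)}; these do not
#' change the conserved (zeroth and first) moments.
#'
#' @param rho node density (> 0), lattice units.
#' @param u velocity vector (length 2 or 3), lattice units.
#' @param stencil an [build_stencil()] object.
#' @return numeric vector of Q populations in the stencil's velocity order.
#' @examples
#' st <- build_stencil(2)
#' f <- equilibrium(1, c(0, 0), st)
#' all.equal(f, st$weights)   # TRUE: at rest, f_i = w_i * rho
#' @export
equilibrium <- function(rho, u, stencil) {
  if (!(is.numeric(rho) && length(rho) == 1L && rho > 0)) {
    stop("rho must be a single positive number")
  }
  stopifnot(length(u) == stencil$dimension)
  cpp_equilibrium(rho, as.numeric(u), stencil$dimension)
}

#' Central-moment transform
#'
#' Maps populations to the full set of central moments
#' \eqn{k_{x^m y^n z^p} = \sum_i f_i (c_{x,i}-u_x)^m (c_{y,i}-u_y)^n
#' (c_{z,i}-u_z)^p}, exponents in \{0, 1, 2\} per axis (monomial ordering,
#' see [build_stencil()]).  The transform is a linear bijection;
#' [from_central_moments()] inverts it to round-off.
#'
#' @param f Q-vector of populations.
#' @param u velocity used as the frame shift.
#' @param stencil an [build_stencil()] object.
#' @return named numeric Q-vector of central moments (monomial ordering).
#' @export
to_central_moments <- function(f, u, stencil) {
  stopifnot(length(f) == stencil$Q, length(u) == stencil$dimension)
  k <- cpp_to_central(as.numeric(f), as.numeric(u), stencil$dimension)
  names(k) <- monomial_labels(stencil$dimension)
  k
}

#' @rdname to_central_moments
#' @param k Q-vector of central moments in monomial ordering.
#' @export
from_central_moments <- function(k, u, stencil) {
  stopifnot(length(k) == stencil$Q, length(u) == stencil$dimension)
  cpp_from_central(as.numeric(k), as.numeric(u), stencil$dimension)
}

monomial_labels <- function(dimension) {
  e <- c("0", "1", "2")
  if (dimension == 2L) {
    as.vector(t(outer(e, e, function(m, n) paste0("k", m, n))))
  } else {
    g <- expand.grid(p = e, n = e, m = e)
    paste0("k", g$m, g$n, g$p)
  }
}

#' Central-moment collision
#'
#' Relaxes each central moment towards its equilibrium value,
#' `k* = k + omega * (k_eq - k)`, on the combined moment basis of
#' [relaxation_frequencies()], then maps back to population space.
#' Density and momentum are conserved exactly.  No body force is applied
#' here; see [apply_force()].
#'
#' @param f Q-vector of populations at one node.
#' @param u velocity of the moving frame (normally `sum(c_i f_i) / rho`,
#'   half-force corrected when a body force is active).
#' @param rv an [relaxation_frequencies()] object (or any `lbm_relaxation`
#'   with a custom `omega` vector).
#' @return post-collision Q-vector.
#' @export
collide <- function(f, u, rv) {
  dim <- rv$dimension
  stopifnot(length(f) == if (dim == 2L) 9L else 27L, length(u) == dim)
  if (any(!is.finite(f))) stop("populations must be finite")
  cpp_collide_cm(as.numeric(f), as.numeric(u), as.numeric(rv$omega), dim)
}

#' Guo body-force step
#'
#' Adds the central-moment form of the Guo forcing term to a post-collision
#' population vector: each forcing moment is scaled by `1 - omega/2` with
#' the omega of its moment group, so one full time step adds exactly `F`
#' of momentum per unit volume.  The macroscopic velocity consistent with
#' this forcing carries the half-force correction
#' `u = (sum(c_i f_i) + F/2) / rho`, which this function returns.
#'
#' @param f post-collision Q-vector.
#' @param F body-force density vector (lattice units).
#' @param rho node density.
#' @param u half-force-corrected node velocity (the same `u` passed to
#'   [collide()]).
#' @param rv an [relaxation_frequencies()] object.
#' @return list with `f` (forced populations) and `u` (the corrected
#'   velocity, returned unchanged for convenience of pipelining).
#' @export
apply_force <- function(f, F, rho, u, rv) {
  dim <- rv$dimension
  stopifnot(length(F) == dim, length(u) == dim)
  CF <- cpp_force_cm(as.numeric(u), as.numeric(F), dim)
  h <- 1 - 0.5 * omega_monomial(rv)
  df <- cpp_from_central(h * CF, as.numeric(u), dim)
  list(f = f + df, u = u)
}

# combined-ordering omega mapped onto the monomial basis; the diagonal
# second-order moments have zero forcing moments, so any group member's
# omega may stand for them
omega_monomial <- function(rv) {
  om <- rv$omega
  if (rv$dimension == 2L) {
    # monomial order: k00 k01 k02 k10 k11 k12 k20 k21 k22
    c(om["k00"], om["k01"], om["k20+k02"], om["k10"], om["k11"],
      om["k12"], om["k20+k02"], om["k21"], om["k22"])
  } else {
    lab <- monomial_labels(3L)
    out <- numeric(27)
    for (i in seq_along(lab)) {
      l <- lab[i]
      out[i] <- if (l %in% names(om)) {
        om[l]
      } else if (l %in% c("k200", "k020", "k002")) {
        om["k200+k020+k002"]
      } else stop("unmapped moment ", l)
    }
    out
  }
}

#' Distribution field over a masked grid
#'
#' The solver's state: per-node populations over a rectangular grid with a
#' solid mask.  Nodes are initialised at equilibrium with density `rho` and
#' zero velocity; solid nodes hold zeros (they only relay bounce-back
#' populations).
#'
#' @param geom a [pore_geometry()] object.
#' @param rho initial density (default 1).
#' @return object of class `lbm_field`: list with `f` (array of dimension
#'   `c(grid dims, Q)`), `solid`, `stencil`.
#' @export
lbm_field <- function(geom, rho = 1) {
  st <- build_stencil(length(dim(geom$solid)))
  dims <- dim(geom$solid)
  f <- array(0, c(dims, st$Q))
  feq <- equilibrium(rho, numeric(st$dimension), st)
  fluid <- !geom$solid
  for (q in seq_len(st$Q)) {
    slice <- array(0, dims)
    slice[fluid] <- feq[q]
    if (st$dimension == 2L) f[, , q] <- slice else f[, , , q] <- slice
  }
  structure(list(f = f, solid = geom$solid, stencil = st),
            class = "lbm_field")
}

q_slice <- function(f, q, dim) {
  if (dim == 2L) f[, , q] else f[, , , q]
}

`q_slice<-` <- function(f, q, dim, value) {
  if (dim == 2L) f[, , q] <- value else f[, , , q] <- value
  f
}

shift_array <- function(x, by) {
  # periodic shift: result[i + by] = x[i]
  dims <- dim(x)
  idx <- lapply(seq_along(dims), function(d) {
    n <- dims[d]
    ((seq_len(n) - 1 - by[d]) %% n) + 1
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Streaming step
#'
#' Pure periodic advection: `f_i(x + c_i) <- f_i(x)` for every direction,
#' wrapping around the domain.  Walls are realised beforehand by
#' [halfway_bounce_back()], which loads reflected populations into the
#' solid nodes so that this shift delivers them back into the fluid.
#'
#' @param field an [lbm_field()] object (post-collision).
#' @return the streamed field.
#' @export
stream <- function(field) {
  st <- field$stencil
  for (q in seq_len(st$Q)) {
    ci <- st$velocities[q, ]
    field$f <- `q_slice<-`(field$f, q, st$dimension,
                           shift_array(q_slice(field$f, q, st$dimension), ci))
  }
  field
}

#' Half-way bounce-back boundary rule
#'
#' For every fluid node `x` and direction `i` whose neighbour `x + c_i` is
#' solid, the post-collision population `f_i*(x)` is reflected into the
#' opposite slot of the solid node, so that the subsequent [stream()]
#' returns it to `x` travelling along `-c_i`.  The no-slip wall sits
#' half-way along each cut link.
#'
#' @param field an [lbm_field()] object holding post-collision populations.
#' @return the field with reflected populations loaded into solid nodes.
#' @export
halfway_bounce_back <- function(field) {
  st <- field$stencil
  dim <- st$dimension
  solid <- field$solid
  if (!any(solid)) return(field)
  Q <- st$Q
  for (q in seq_len(Q)) {
    ci <- st$velocities[q, ]
    # neighbour x + c is solid and x is fluid
    nb_solid <- shift_array(solid, -ci)   # nb_solid[x] = solid[x + c]
    src <- !solid & nb_solid
    if (!any(src)) next
    fq <- q_slice(field$f, q, dim)
    fopp <- q_slice(field$f, Q + 1 - q, dim)
    # write f_i*(x) into slot (Q+1-q) of node x + c
    dest <- shift_array(src, ci)
    shifted <- shift_array(fq, ci)   # shifted[x + c] = f_i*(x)
    fopp[dest] <- shifted[dest]
    field$f <- `q_slice<-`(field$f, Q + 1 - q, dim, fopp)
  }
  field
}

#' Macroscopic fields
#'
#' Density `rho = sum_i f_i`, half-force corrected velocity
#' `u = (sum_i c_i f_i + F/2) / rho`, and pressure `P = cs2 * rho`,
#' evaluated on fluid nodes (solid nodes report zero).
#'
#' @param field an [lbm_field()] object.
#' @param F body-force density vector (defaults to zero).
#' @return list with `rho`, `u` (list of component arrays) and `P`.
#' @export
macroscopics <- function(field, F = NULL) {
  st <- field$stencil
  dim <- st$dimension
  if (is.null(F)) F <- numeric(dim)
  dims <- utils::head(base::dim(field$f), -1)
  rho <- array(0, dims)
  mom <- lapply(seq_len(dim), function(d) array(0, dims))
  for (q in seq_len(st$Q)) {
    fq <- q_slice(field$f, q, dim)
    rho <- rho + fq
    for (d in seq_len(dim)) {
      if (st$velocities[q, d] != 0) {
        mom[[d]] <- mom[[d]] + st$velocities[q, d] * fq
      }
    }
  }
  fluid <- !field$solid
  u <- lapply(seq_len(dim), function(d) {
    out <- array(0, dims)
    out[fluid] <- (mom[[d]][fluid] + 0.5 * F[d]) / rho[fluid]
    out
  })
  list(rho = rho, u = u, P = st$cs2 * rho)
}
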