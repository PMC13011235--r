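#' Lattice stencil constants
#'
#' Builds the discrete velocity set, quadrature weights and sound speed of
#' the standard D2Q9 (two dimensions) or D3Q27 (three dimensions) lattice.
#' Lattice spacing and time step are unity throughout, so the squared sound
#' speed is `cs2 = 1/3`.
#'
#' @details
#' The velocity ordering is fixed and shared by every function in the
#' package: direction `q` (1-based) corresponds to the integer vector
#' `(a, b)` with `q - 1 = (a + 1) * 3 + (b + 1)` in 2D, and `(a, b, c)` with
#' `q - 1 = (a + 1) * 9 + (b + 1) * 3 + (c + 1)` in 3D, where each component
#' runs over \{-1, 0, 1\}.  The opposite of direction `q` is `Q + 1 - q`.
#'
#' Central moments are reported on two bases.  The *monomial* basis indexes
#' the moment \eqn{k_{x^m y^n z^p}} at position `m*3 + n` (2D) or
#' `m*9 + n*3 + p` (3D), zero-based, with exponents in \{0, 1, 2\}.  The
#' *combined* basis groups the second-order moments into trace and
#' deviatoric combinations; it is the ordering used by
#' [relaxation_frequencies()] and is stored in `moment_labels`.
#'
#' @param dimension 2 or 3.
#' @return An object of class `lbm_stencil`: a list with `dimension`, `Q`,
#'   `velocities` (Q x dimension integer matrix), `weights`, `cs2` and
#'   `moment_labels` (the combined moment ordering).
#' @examples
#' st <- build_stencil(2)
#' sum(st$weights)                       # 1
#' colSums(st$weights * st$velocities)   # zero vector
#' @export
build_stencil <- function(dimension) {
  if (!dimension %in% c(2L, 3L)) {
    stop("unsupported dimension: ", dimension, " (must be 2 or 3)")
  }
  dimension <- as.integer(dimension)
  comp <- c(-1L, 0L, 1L)
  if (dimension == 2L) {
    grid <- expand.grid(b = comp, a = comp)   # b fastest, matching q ordering
    vel <- cbind(grid$a, grid$b)
    labels <- c("k00", "k10", "k01", "k20+k02", "k20-k02", "k11",
                "k21", "k12", "k22")
    roles <- c("conserved", "conserved", "conserved", "bulk", "viscous",
               "viscous", "magic", "magic", "higher")
  } else {
    grid <- expand.grid(c = comp, b = comp, a = comp)
    vel <- cbind(grid$a, grid$b, grid$c)
    labels <- c("k000", "k100", "k010", "k001",
                "k110", "k101", "k011", "k200-k020", "k200-k002",
                "k200+k020+k002",
                "k210", "k201", "k120", "k021", "k102", "k012", "k111",
                "k220", "k202", "k022", "k211", "k121", "k112",
                "k221", "k212", "k122", "k222")
    roles <- c(rep("conserved", 4), rep("viscous", 5), "bulk",
               rep("magic", 7), rep("higher", 10))
  }
  w <- apply(vel, 1, function(ci) prod(ifelse(ci == 0, 2 / 3, 1 / 6)))
  structure(
    list(dimension = dimension, Q = nrow(vel), velocities = vel,
         weights = w, cs2 = 1 / 3,
         moment_labels = labels, moment_roles = roles),
    class = "lbm_stencil"
  )
}

#' @export
print.lbm_stencil <- function(x, ...) {
  cat(sprintf("D%dQ%d lattice stencil (cs2 = 1/3, dx = dt = 1)\n",
              x$dimension, x$Q))
  invisible(x)
}

#' Per-moment relaxation frequencies
#'
#' Builds the relaxation-frequency vector of the non-orthogonal
#' central-moment collision operator.  Second-order shear moments carry the
#' viscous frequency `1/tau`; the third-order moments carry the "magic"
#' frequency `8 * (2 - 1/tau) / (8 - 1/tau)`, which pins the half-way
#' bounce-back wall exactly mid-link and makes permeability independent of
#' `tau`.  Remaining frequencies are 1, except the D2Q9 second-order trace
#' (1.6) and fourth-order moment (1.8).
#'
#' @param tau relaxation time, must exceed 0.5.
#' @param stencil an [build_stencil()] object.
#' @return An object of class `lbm_relaxation`: list with `tau`, `omega`
#'   (length Q, combined moment ordering, see [build_stencil()]), and
#'   `roles` tagging each entry.
#' @examples
#' rv <- relaxation_frequencies(1, build_stencil(2))
#' rv$omega[rv$roles == "magic"]   # 8/7
#' @export
relaxation_frequencies <- function(tau, stencil) {
  if (!(is.numeric(tau) && length(tau) == 1L && tau > 0.5)) {
    stop("tau must be a single number > 0.5 (tau <= 0.5 gives non-positive viscosity)")
  }
  roles <- stencil$moment_roles
  s <- 1 / tau
  omega <- numeric(stencil$Q)
  omega[roles == "conserved"] <- 1
  omega[roles == "viscous"] <- s
  omega[roles == "magic"] <- 8 * (2 - s) / (8 - s)
  if (stencil$dimension == 2L) {
    omega[roles == "bulk"] <- 1.6
    omega[roles == "higher"] <- 1.8
  } else {
    omega[roles == "bulk"] <- 1
    omega[roles == "higher"] <- 1
  }
  names(omega) <- stencil$moment_labels
  structure(list(tau = tau, omega = omega, roles = roles,
                 dimension = stencil$dimension),
            class = "lbm_relaxation")
}

#' @export
print.lbm_relaxation <- function(x, ...) {
  cat(sprintf("central-moment relaxation vector (tau = %g)\n", x$tau))
  print(x$omega)
  invisible(x)
}

#' Kinematic viscosity of the lattice fluid
#'
#' `nu = cs2 * (tau - 1/2)` in lattice units; the dynamic viscosity is
#' `mu = rho * nu`.
#'
#' @param tau relaxation time (> 0.5).
#' @return kinematic viscosity in lattice units.
#' @examples
#' viscosity(1)   # 1/6
#' viscosity(2)   # 1/2
#' @export
viscosity <- function(tau) {
  if (!(is.numeric(tau) && all(tau > 0.5))) {
    stop("tau must exceed 0.5: viscosity cs2*(tau - 1/2) must be positive")
  }
  (tau - 0.5) / 3
}
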