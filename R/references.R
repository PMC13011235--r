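#' Analytic plane Poiseuille profile
#'
#' Velocity profile of steady force-driven flow between parallel no-slip
#' walls a distance `L` apart: `u(x) = 4 * umax * x * (L - x) / L^2`,
#' with the maximum `umax` on the centreline.
#'
#' @param x wall-normal position(s), `0 <= x <= L` (0 at one wall).
#' @param umax centreline velocity.
#' @param L channel width.
#' @return streamwise velocity at `x`.
#' @export
poiseuille_reference <- function(x, umax, L) {
  4 * umax * x * (L - x) / L^2
}

#' Gebart transverse permeability of a hexagonal cylinder array
#'
#' Closed-form dimensionless permeability `k / R^2` for creeping flow
#' perpendicular to a hexagonal array of cylinders of radius `R` at
#' porosity `phi`:
#' \deqn{k/R^2 = \frac{16}{9\pi\sqrt6}\left(\sqrt{\frac{\pi}{2\sqrt3\,(1-\phi)}} - 1\right)^{5/2}.}
#' The bracket vanishes at the touching-cylinder porosity
#' `1 - pi / (2 sqrt(3))` (about 0.0931), below which the array is closed.
#'
#' @param phi porosity in (0, 1).
#' @return `k / R^2` (dimensionless).
#' @examples
#' gebart_reference(0.8)
#' gebart_reference(1 - pi / (2 * sqrt(3)))   # 0: cylinders touch
#' @export
gebart_reference <- function(phi) {
  stopifnot(all(phi > 0 & phi < 1))
  bracket <- sqrt(pi / (2 * sqrt(3) * (1 - phi))) - 1
  if (any(bracket < 0)) {
    stop("porosity below the touching-cylinder limit 1 - pi/(2*sqrt(3))")
  }
  16 / (9 * pi * sqrt(6)) * bracket^(5 / 2)
}

#' Reference dimensionless FCC permeability
#'
#' The Stokes-flow dimensionless permeability `k / D^2` of the close-packed
#' FCC sphere packing (sphere diameter `D`), `1.7360e-4`, used as the
#' grid-convergence reference for [make_fcc()] simulations.
#'
#' @return `k / D^2`.
#' @export
fcc_reference <- function() 1.7360e-4
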