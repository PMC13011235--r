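#' Tidy a directional permeability study
#'
#' @param x a [directional_permeability()] result.
#' @param ... unused.
#' @return a tibble with one row per flow direction.
#' @export
tidy.directional_study <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out
}

#' @rdname tidy.directional_study
#' @return `glance`: a one-row tibble with the anisotropy ratios and the
#'   worst relative mismatch between paired opposite directions.
#' @export
glance.directional_study <- function(x, ...) {
  ratios <- attr(x, "ratios")
  d <- tibble::as_tibble(x)
  axes <- unique(substr(d$direction, 1, 1))
  rev_spread <- vapply(axes, function(ax) {
    k <- d$k_lattice[substr(d$direction, 1, 1) == ax]
    # the relative spread is meaningless for non-conducting directions
    if (length(k) < 2 || any(is.na(k)) || mean(abs(k)) < 1e-10) return(NA_real_)
    abs(diff(k)) / mean(k)
  }, numeric(1))
  out <- tibble::tibble(partial = attr(x, "partial"),
                        max_reversal_spread = max(rev_spread, na.rm = TRUE))
  for (nm in names(ratios)) out[[nm]] <- unname(ratios[nm])
  out
}

#' Tidy an ensemble study
#'
#' @param x an [ensemble_study()] result.
#' @param ... unused.
#' @return the per-descriptor Spearman correlation tibble.
#' @export
tidy.ensemble_study <- function(x, ...) x$correlations

#' @rdname tidy.ensemble_study
#' @export
glance.ensemble_study <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$data), n_failed = x$n_failed,
                 k_darcy_median = stats::median(x$data$k_darcy, na.rm = TRUE))
}

#' Tidy a flow solution
#'
#' @param x a [run_to_steady_state()] result.
#' @param ... unused.
#' @return `glance`: one-row tibble with convergence diagnostics.
#' @export
glance.flow_solution <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 el2 = x$el2, n_fluid = x$n_fluid, rho_mean = x$rho_mean)
}
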