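#' Plot the velocity-magnitude field of a 2D solution
#'
#' Raster of |u| over the domain (solid voxels blank), the standard way of
#' inspecting preferential flow paths.
#'
#' @param object a [run_to_steady_state()] solution on a 2D geometry.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.flow_solution <- function(object, ...) {
  if (length(object$dims) != 2L) {
    stop("autoplot is implemented for 2D solutions; slice 3D fields first")
  }
  umag <- sqrt(object$u[[1]]^2 + object$u[[2]]^2)
  df <- expand.grid(x = seq_len(object$dims[1]), y = seq_len(object$dims[2]))
  df$u <- as.vector(umag)
  df$u[as.vector(object$rho) == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$u)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "black",
                                  name = "|u| (lu)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot an ensemble correlation report
#'
#' Bar chart of the Spearman coefficient of each structural descriptor
#' against permeability, annotated with significance stars.
#'
#' @param object an [ensemble_study()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ensemble_study <- function(object, ...) {
  d <- object$correlations
  d$descriptor <- stats::reorder(d$descriptor, d$rs)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$descriptor, y = .data$rs)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars),
                       vjust = ifelse(d$rs >= 0, -0.3, 1.2)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rs with permeability")
}

#' Plot a pore-size distribution
#'
#' Histogram of the local-thickness map (volume-weighted pore-size
#' distribution) with the D10/D50/D90 quantiles marked.
#'
#' @param thickness a [local_thickness()] map.
#' @return a ggplot object.
#' @export
plot_psd <- function(thickness) {
  q <- psd_quantiles(thickness)
  v <- as.numeric(thickness)
  v <- v[!is.na(v)]
  df <- data.frame(thickness = v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$thickness)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(count) /
                                           sum(ggplot2::after_stat(count))),
                            bins = 40) +
    ggplot2::geom_vline(xintercept = unname(q), linetype = "dashed") +
    ggplot2::labs(x = "local thickness", y = "volume fraction")
}
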