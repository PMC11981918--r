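#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spatial shape histogram
#'
#' Shape-cluster by radial-bin count matrix as a tile map.
#'
#' @param object a `spatial_shape_histogram`.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.spatial_shape_histogram <- function(object, ...) {
  df <- as.data.frame(as.table(object$counts))
  names(df) <- c("shape", "radial_bin", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$radial_bin, y = .data$shape,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "radial bin (15 µm steps)", y = "shape cluster",
                  fill = "PSS count") +
    ggplot2::theme_minimal()
}

#' Plot a synapse-soma targeting profile
#'
#' Angle/distance scatter with the axon-initial-segment window marked; the
#' signature view in which chandelier axons stand out.
#'
#' @param object a [targeting_profile()].
#' @param angle_window,r_max_um the AIS window, drawn as guides.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.targeting_profile <- function(object, angle_window = c(160, 180),
                                       r_max_um = 60, ...) {
  df <- object[object$known_target, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$r_um)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = angle_window[1], linetype = 2) +
    ggplot2::geom_hline(yintercept = r_max_um, linetype = 2) +
    ggplot2::labs(x = "ϕ (degrees; 180 = below soma)",
                  y = "r (µm)") +
    ggplot2::xlim(0, 180) +
    ggplot2::theme_minimal()
}

#' Plot per-subclass density maps
#'
#' @param density_map output of [subclass_density_map()].
#' @return A ggplot object, one panel per subclass.
#' @export
plot_density_map <- function(density_map) {
  ggplot2::ggplot(density_map,
                  ggplot2::aes(x = .data$bin_x, y = .data$bin_z,
                               fill = .data$density_per_mm2)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~leaf_label) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x bin", y = "z bin", fill = "cells / mm²") +
    ggplot2::theme_minimal()
}
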