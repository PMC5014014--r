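# ggplot2 graphics for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a richness surface on its hexagon grid
#'
#' @param object A `richness_surface` (see [relative_richness()]).
#' @param grid The `hex_grid` it was computed on.
#' @param region Optional `region_polygon` outline to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot richness_surface
#' @export
autoplot.richness_surface <- function(object, grid, region = NULL, ...) {
  verts <- hex_vertices(grid, object$cell)
  verts$richness <- object$richness[match(verts$cell, object$cell)]
  p <- ggplot2::ggplot(
    verts,
    ggplot2::aes(x = .data$lon, y = .data$lat, group = .data$cell,
                 fill = .data$richness)
  ) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::scale_fill_viridis_c(name = "relative\nrichness") +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude")
  if (!is.null(region)) {
    ring <- as.data.frame(region$rings[[1]])
    ring <- rbind(ring, ring[1, ])
    p <- p + ggplot2::geom_path(
      data = ring,
      ggplot2::aes(x = .data$lon, y = .data$lat),
      inherit.aes = FALSE, linewidth = 0.6
    )
  }
  p
}

#' Plot a fitted 1-D smooth and its peak interval
#'
#' Centred smooth estimate with a +/- 2 s.e. ribbon (an approximate 95%
#' confidence band) and the peak location marked.
#'
#' @param object A `smooth_peak`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot smooth_peak
#' @export
autoplot.smooth_peak <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$value, y = .data$est)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$est - 2 * .data$se,
                   ymax = .data$est + 2 * .data$se),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$peak, linetype = 2) +
    ggplot2::annotate("rect", xmin = object$lower, xmax = object$upper,
                      ymin = -Inf, ymax = Inf, alpha = 0.1) +
    ggplot2::labs(x = object$term, y = "partial effect")
}

#' Plot an empirical variogram with its permutation envelope
#'
#' @param object A `variogram` (see [residual_variogram()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot variogram
#' @export
autoplot.variogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dist_mid, y = .data$gamma)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$env_lo, ymax = .data$env_hi),
      fill = "grey85"
    ) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (km)", y = "semivariance")
}
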