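# ggplot2 visualisations: the color-coded rod map, circular (polar) angle
# plots per region and tilt, the smoothed angle-field surface, and regional
# spacing profiles.

CATEGORY_FILLS <- c(inner_mesial = "black", inner_lateral = "red3",
                    outer = "blue3", cej = "magenta3")

#' Plot the rod map of an analysis
#'
#' Rod centroids in the section plane, colored by category, with the DEJ,
#' layer-boundary and surface polylines.
#'
#' @param object A `rod_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rod_analysis <- function(object, ...) {
  g <- object$geometry
  ggplot2::ggplot(object$rods,
                  ggplot2::aes(.data$centroid_x, .data$centroid_y)) +
    ggplot2::geom_path(data = g$dej, ggplot2::aes(.data$x, .data$y),
                       linewidth = 0.3, color = "grey40") +
    ggplot2::geom_path(data = g$surface, ggplot2::aes(.data$x, .data$y),
                       linewidth = 0.3, color = "grey40") +
    ggplot2::geom_path(data = g$layer_boundary,
                       ggplot2::aes(.data$x, .data$y),
                       linewidth = 0.2, linetype = 2, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$category), size = 0.3) +
    ggplot2::scale_color_manual(values = CATEGORY_FILLS) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px, lateral → mesial)", y = "y (px)",
                  color = "category") +
    ggplot2::theme_minimal()
}

#' Plot a synthetic map with its ground truth
#'
#' @param object An `enamel_map` carrying a `truth` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enamel_map <- function(object, ...) {
  if (is.null(object$truth)) abort("map carries no ground-truth records")
  ggplot2::ggplot(object$truth,
                  ggplot2::aes(.data$true_x_px, .data$true_y_px,
                               color = .data$category)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_color_manual(values = CATEGORY_FILLS) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' Circular plot of rod tilt angles by region
#'
#' Polar histograms of Feret angles per region (lateral 1 to mesial 4),
#' faceted by category/tilt, mirroring the classic circular summaries of
#' orientation data. Angles run counterclockwise from 3 o'clock.
#'
#' @param rods Per-rod tibble (e.g. `tidy(analysis, "rods")`).
#' @param binwidth_deg Histogram bin width, degrees.
#' @return A ggplot.
#' @export
plot_circular_angles <- function(rods, binwidth_deg = 10) {
  ggplot2::ggplot(rods, ggplot2::aes(.data$feret_angle_deg,
                                     fill = factor(.data$region))) +
    ggplot2::geom_histogram(binwidth = binwidth_deg, boundary = 0,
                            position = "stack") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "Feret angle (deg, CCW from 3 o'clock)",
                  fill = "region") +
    ggplot2::theme_minimal()
}

#' Smoothed angle-field surface
#'
#' Distance-weighted least-squares surface of rod angles over normalized
#' position (x: lateral to mesial; y: depth fraction DEJ to surface).
#'
#' @param rods Per-rod tibble with `norm_x`, `depth_fraction`,
#'   `feret_angle_deg`.
#' @param ... Passed to [dwls_surface()].
#' @return A ggplot.
#' @export
plot_angle_surface <- function(rods, ...) {
  surf <- dwls_surface(tibble(x = rods$norm_x, y = rods$depth_fraction,
                              value = rods$feret_angle_deg), ...)
  ggplot2::ggplot(surf, ggplot2::aes(.data$x, .data$y,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "angle (deg)") +
    ggplot2::labs(x = "normalized x (lateral → mesial)",
                  y = "depth fraction (DEJ → surface)") +
    ggplot2::theme_minimal()
}

#' Regional spacing profile
#'
#' Mean inter-centroid spacing (with SD ribbons) across the four regions,
#' per category and tilt.
#'
#' @param spacing Spacing table (e.g. `tidy(analysis, "spacing")`).
#' @return A ggplot.
#' @export
plot_spacing_profile <- function(spacing) {
  spacing <- mutate(spacing,
                    series = ifelse(is.na(.data$tilt), .data$category,
                                    paste(.data$category, .data$tilt)))
  ggplot2::ggplot(spacing,
                  ggplot2::aes(.data$region, .data$spacing_mean_um,
                               color = .data$series, group = .data$series)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$spacing_mean_um - .data$spacing_sd_um,
      ymax = .data$spacing_mean_um + .data$spacing_sd_um,
      fill = .data$series), alpha = 0.15, color = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "region (1 lateral → 4 mesial)",
                  y = "spacing (µm)") +
    ggplot2::theme_minimal()
}
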