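#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Side view of a particle partition
#'
#' x-z scatter of the particles coloured by top/middle/bottom label, with
#' the fitted interfaces drawn along the mid-y section when a film is
#' supplied.
#'
#' @param object An `awi_partition`.
#' @param film Optional `thin_film` for the interface traces.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot awi_partition
#' @export
autoplot.awi_partition <- function(object, film = NULL, ...) {
  p <- ggplot2::ggplot(object$particles,
                       ggplot2::aes(x = .data$x, y = .data$z,
                                    colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(top = "#E6B800", middle = "grey55", bottom = "#2E8B57")) +
    ggplot2::labs(x = "x (nm)", y = "z (nm)", colour = NULL,
                  title = sprintf("Bound fraction %.2f at %.3g nm",
                                  object$bound_fraction, object$threshold_nm)) +
    ggplot2::theme_minimal()
  if (!is.null(film)) {
    xs <- seq(film$bounds$xlim[1], film$bounds$xlim[2], length.out = 200)
    ymid <- mean(film$bounds$ylim)
    lines <- dplyr::bind_rows(
      tibble(x = xs, z = surface_eval(film$top, xs, ymid), face = "top"),
      tibble(x = xs, z = surface_eval(film$bottom, xs, ymid), face = "bottom"))
    p <- p + ggplot2::geom_line(
      data = lines, ggplot2::aes(x = .data$x, y = .data$z, group = .data$face),
      inherit.aes = FALSE, colour = "grey30", linetype = 2)
  }
  p
}

#' Thickness map of a thin film
#'
#' @param object A `thin_film`.
#' @param eval_n Raster resolution.
#' @param ... Unused.
#' @return A ggplot raster of top - bottom over the bounds.
#' @method autoplot thin_film
#' @export
autoplot.thin_film <- function(object, eval_n = 100, ...) {
  xs <- seq(object$bounds$xlim[1], object$bounds$xlim[2], length.out = eval_n)
  ys <- seq(object$bounds$ylim[1], object$bounds$ylim[2], length.out = eval_n)
  g <- as_tibble(expand.grid(x = xs, y = ys))
  g$thickness <- surface_eval(object$top, g$x, g$y) -
    surface_eval(object$bottom, g$x, g$y)
  ggplot2::ggplot(g, ggplot2::aes(.data$x, .data$y, fill = .data$thickness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "thickness (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Mollweide rendering of an orientation density map
#'
#' Equal-area Mollweide projection of the gridded PDF; the colour scale
#' spans \[0, max density\].
#'
#' @param object An `orientation_pdf`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot orientation_pdf
#' @export
autoplot.orientation_pdf <- function(object, ...) {
  g <- object$grid
  xy <- mollweide_xy(g$lon_deg, g$lat_deg)
  g$px <- xy$x
  g$py <- xy$y
  ggplot2::ggplot(g, ggplot2::aes(.data$px, .data$py, colour = .data$pdf_sr)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_viridis_c(name = expression(PDF ~ (sr^-1)),
                                    limits = c(0, max(g$pdf_sr))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Orientation PDF (%s, bw %g deg, n = %d)",
                                  object$symmetry, object$bandwidth_deg,
                                  object$n_particles)) +
    ggplot2::theme_void()
}

#' Observed vs null-model distance densities
#'
#' @param object A `null_comparison`.
#' @param ... Unused.
#' @return A ggplot of the binned distance-to-nearer-interface densities.
#' @method autoplot null_comparison
#' @export
autoplot.null_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$bins, c("density_observed", "density_model"),
    names_to = "series", values_to = "density", names_prefix = "density_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin_lo, y = .data$density,
                                     fill = .data$series)) +
    ggplot2::geom_col(position = "dodge",
                      width = object$bins$bin_hi[1] - object$bins$bin_lo[1]) +
    ggplot2::labs(x = "distance to nearer interface (nm)",
                  y = expression(density ~ (nm^-1)), fill = NULL,
                  title = sprintf("max |CDF diff| %.3f (%.3f beyond %g nm)",
                                  object$stat_overall, object$stat_restricted,
                                  object$restrict_above_nm)) +
    ggplot2::theme_minimal()
}
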