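#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_surface tidy(): one row per polynomial coefficient.
#' @param x,... Broom-generic arguments.
#' @method tidy fitted_surface
#' @export
tidy.fitted_surface <- function(x, ...) {
  tibble(term = names(x$coeffs), estimate = unname(x$coeffs),
         side = x$side, order = x$order)
}

#' @describeIn fit_surface glance(): one-row fit summary.
#' @method glance fitted_surface
#' @export
glance.fitted_surface <- function(x, ...) {
  tibble(side = x$side, order = x$order, rms_residual = x$rms_residual,
         n_support = nrow(x$support_points))
}

#' @describeIn build_film tidy(): coefficients of both interfaces.
#' @param x,... Broom-generic arguments.
#' @method tidy thin_film
#' @export
tidy.thin_film <- function(x, ...) {
  dplyr::bind_rows(tidy(x$top), tidy(x$bottom))
}

#' @describeIn build_film glance(): one-row film summary.
#' @method glance thin_film
#' @export
glance.thin_film <- function(x, ...) {
  tibble(mean_thickness_nm = x$mean_thickness_nm,
         top_order = x$top$order, bottom_order = x$bottom$order,
         top_rms = x$top$rms_residual, bottom_rms = x$bottom$rms_residual,
         nx = x$grid$nx, ny = x$grid$ny)
}

#' @describeIn classify_particles tidy(): the per-particle table
#'   (coordinates, signed distances to each interface, label).
#' @param x,... Broom-generic arguments.
#' @method tidy awi_partition
#' @export
tidy.awi_partition <- function(x, ...) {
  as_tibble(x$particles)
}

#' @describeIn classify_particles glance(): one-row summary (threshold,
#'   bound fraction, counts, asymmetry index).
#' @method glance awi_partition
#' @export
glance.awi_partition <- function(x, ...) {
  tibble(n_particles = nrow(x$particles), threshold_nm = x$threshold_nm,
         mean_thickness_nm = x$mean_thickness_nm,
         bound_fraction = x$bound_fraction,
         n_top = x$n_top, n_middle = x$n_middle, n_bottom = x$n_bottom,
         asymmetry_index = x$asymmetry_index)
}

#' @describeIn spherical_kde tidy(): the gridded density table.
#' @param x,... Broom-generic arguments.
#' @method tidy orientation_pdf
#' @export
tidy.orientation_pdf <- function(x, ...) {
  x$grid
}

#' @describeIn spherical_kde glance(): one-row map summary.
#' @method glance orientation_pdf
#' @export
glance.orientation_pdf <- function(x, ...) {
  tibble(n_particles = x$n_particles, bandwidth_deg = x$bandwidth_deg,
         grid_res_deg = x$grid_res_deg, symmetry = x$symmetry,
         expanded = x$expanded, max_pdf_sr = max(x$grid$pdf_sr),
         integral = sum(x$grid$pdf_sr * x$grid$area_sr))
}

#' @describeIn compare_to_observed tidy(): the binned density table.
#' @param x,... Broom-generic arguments.
#' @method tidy null_comparison
#' @export
tidy.null_comparison <- function(x, ...) {
  x$bins
}

#' @describeIn compare_to_observed glance(): the CDF-distance statistics.
#' @method glance null_comparison
#' @export
glance.null_comparison <- function(x, ...) {
  tibble(stat_overall = x$stat_overall, stat_restricted = x$stat_restricted,
         restrict_above_nm = x$restrict_above_nm,
         n_observed = x$n_observed, n_model = x$n_model)
}
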