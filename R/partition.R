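#' Classify particles as interface-bound or bulk
#'
#' Computes each particle's signed closest distance to both fitted
#' interfaces and classes it as bound when the smaller distance magnitude is
#' at or below the threshold. Bound particles are labelled by the nearer
#' surface (ties go to the top); a particle beyond a fitted surface
#' (negative signed distance) is labelled to the surface it exceeds and
#' counts as bound. With `threshold_nm = "auto"` the threshold is 20 nm when
#' the mean film thickness exceeds 80 nm and 10 nm otherwise.
#'
#' @param particles Data frame with columns `x`, `y`, `z` (nm).
#' @param film A [build_film()] / [film_from_coeffs()] result.
#' @param threshold_nm Bound-distance threshold in nm, or `"auto"`.
#' @param mode Distance mode passed to [closest_distance()].
#' @return An `awi_partition`: per-particle tibble (`x`, `y`, `z`, `d_top`,
#'   `d_bottom`, `label`) plus `threshold_nm`, `bound_fraction`, counts
#'   `n_top`/`n_middle`/`n_bottom`, `asymmetry_index` and
#'   `mean_thickness_nm`.
#' @export
classify_particles <- function(particles, film, threshold_nm = "auto",
                               mode = c("euclidean", "vertical")) {
  check_xyz(particles)
  mode <- match.arg(mode)
  if (!inherits(film, "thin_film")) abort("`film` must be a thin_film.")
  if (identical(threshold_nm, "auto")) {
    threshold_nm <- if (film$mean_thickness_nm > 80) 20 else 10
  }
  if (!is.numeric(threshold_nm) || length(threshold_nm) != 1 ||
      threshold_nm <= 0) {
    abort("`threshold_nm` must be a single positive length (nm) or \"auto\".")
  }
  d_top <- closest_distance(particles, film$top, mode = mode)
  d_bottom <- closest_distance(particles, film$bottom, mode = mode)
  pp <- tibble(x = particles$x, y = particles$y, z = particles$z,
               d_top = d_top, d_bottom = d_bottom)
  partition_from_distances(pp, threshold_nm, film$mean_thickness_nm)
}

# labelling rule shared by classify_particles() and repartition()
partition_from_distances <- function(pp, threshold_nm, mean_thickness_nm) {
  outside_top <- pp$d_top < 0
  outside_bottom <- pp$d_bottom < 0
  near_top <- abs(pp$d_top) <= abs(pp$d_bottom)  # tie -> top
  bound <- pmin(abs(pp$d_top), abs(pp$d_bottom)) <= threshold_nm
  label <- ifelse(!bound, "middle", ifelse(near_top, "top", "bottom"))
  label[outside_top] <- "top"
  label[outside_bottom] <- "bottom"
  pp$label <- factor(label, levels = c("top", "middle", "bottom"))
  n_top <- sum(pp$label == "top")
  n_middle <- sum(pp$label == "middle")
  n_bottom <- sum(pp$label == "bottom")
  structure(list(
    particles = pp,
    threshold_nm = threshold_nm,
    mean_thickness_nm = mean_thickness_nm,
    bound_fraction = (n_top + n_bottom) / nrow(pp),
    n_top = n_top, n_middle = n_middle, n_bottom = n_bottom,
    asymmetry_index = abs(n_top - n_bottom) / max(1, n_top + n_bottom)
  ), class = "awi_partition")
}

#' Re-apply a different bound threshold to an existing partition
#'
#' Reuses the stored signed distances, so no surface geometry is recomputed.
#'
#' @param partition An `awi_partition`.
#' @param threshold_nm New positive threshold in nm.
#' @return A new `awi_partition`.
#' @export
repartition <- function(partition, threshold_nm) {
  if (!inherits(partition, "awi_partition")) {
    abort("`partition` must be an awi_partition.")
  }
  if (!is.numeric(threshold_nm) || threshold_nm <= 0) {
    abort("`threshold_nm` must be positive.")
  }
  partition_from_distances(
    partition$particles[c("x", "y", "z", "d_top", "d_bottom")],
    threshold_nm, partition$mean_thickness_nm)
}

#' @export
print.awi_partition <- function(x, ...) {
  cat(sprintf(
    "<awi_partition> %d particles, threshold %.3g nm (film %.3g nm thick)\n",
    nrow(x$particles), x$threshold_nm, x$mean_thickness_nm))
  cat(sprintf("  bound %.1f%% (top %d / middle %d / bottom %d), asymmetry %.2f\n",
              100 * x$bound_fraction, x$n_top, x$n_middle, x$n_bottom,
              x$asymmetry_index))
  invisible(x)
}

#' Summarize partitions across tomograms
#'
#' Per-condition mean and SD of the bound fraction and asymmetry index,
#' weighting tomograms equally; singleton groups report SD = 0. Per-tomogram
#' values are returned alongside so alternative weightings can be
#' recomputed.
#'
#' @param partitions List of `awi_partition` objects.
#' @param groups Character/factor vector of condition keys, one per
#'   partition (default: a single group).
#' @return A list of two tibbles: `summary` (one row per group) and
#'   `per_tomogram`.
#' @export
summarize_partitions <- function(partitions, groups = NULL) {
  if (!is.list(partitions) || length(partitions) == 0 ||
      !all(vapply(partitions, inherits, logical(1), "awi_partition"))) {
    abort("`partitions` must be a non-empty list of awi_partition objects.")
  }
  if (is.null(groups)) groups <- rep("all", length(partitions))
  if (length(groups) != length(partitions)) {
    abort("`groups` must have one key per partition.")
  }
  per <- purrr::imap(partitions, function(p, i) tibble(
    group = as.character(groups[[i]]),
    tomogram = i,
    n_particles = nrow(p$particles),
    bound_fraction = p$bound_fraction,
    asymmetry_index = p$asymmetry_index,
    n_top = p$n_top, n_bottom = p$n_bottom,
    threshold_nm = p$threshold_nm,
    mean_thickness_nm = p$mean_thickness_nm
  )) |> dplyr::bind_rows()
  summary <- per |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_tomograms = dplyr::n(),
      mean_bound_fraction = mean(.data$bound_fraction),
      sd_bound_fraction = if (dplyr::n() > 1) sd(.data$bound_fraction) else 0,
      mean_asymmetry = mean(.data$asymmetry_index),
      sd_asymmetry = if (dplyr::n() > 1) sd(.data$asymmetry_index) else 0,
      top_share_bound = sum(.data$n_top) / max(1, sum(.data$n_top) + sum(.data$n_bottom)),
      .groups = "drop"
    )
  list(summary = summary, per_tomogram = per)
}
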