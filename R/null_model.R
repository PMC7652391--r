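#' Simulate ideal (random-placement) particle behaviour in a film
#'
#' Draws particle coordinates uniformly between the two fitted interfaces —
#' x/y uniform over the analysis area, z uniform between `bottom(x, y)` and
#' `top(x, y)` at each sampled (x, y) — at the applied solution
#' concentration, with no affinity for either interface. The same
#' [closest_distance()] machinery used for real particles supplies the
#' per-particle distances, so the run can be compared directly with an
#' observed partition.
#'
#' @param film A `thin_film`.
#' @param applied_uM Applied concentration in uM (> 0).
#' @param seed Integer RNG seed; the run is fully reproducible given it.
#' @param count_mode `"poisson"` (default): particle number drawn as
#'   Poisson(expected); `"fixed"`: rounded expectation, for exact
#'   reproducibility.
#' @param mode Distance mode passed to [closest_distance()].
#' @return A `null_model_run`: tibble `particles` (`x`, `y`, `z`, `d_top`,
#'   `d_bottom`, `d_min`), `n_generated`, `expected_count`, `seed`,
#'   `applied_uM` and the film volume used.
#' @export
simulate_null <- function(film, applied_uM, seed = 1,
                          count_mode = c("poisson", "fixed"),
                          mode = c("euclidean", "vertical")) {
  count_mode <- match.arg(count_mode)
  mode <- match.arg(mode)
  if (!inherits(film, "thin_film")) abort("`film` must be a thin_film.")
  if (!is.numeric(applied_uM) || applied_uM <= 0) {
    abort("`applied_uM` must be positive.")
  }
  volume <- film_volume(film)
  expected <- applied_uM * volume * UM_PER_NM3
  set.seed(as.integer(seed))
  if (expected < 1) {
    warn(sprintf("expected particle count %.3g < 1; drawing a Poisson count.",
                 expected))
    count_mode <- "poisson"
  }
  n <- if (count_mode == "fixed") round(expected) else rpois(1, expected)
  xlim <- film$bounds$xlim
  ylim <- film$bounds$ylim
  coords <- sample_in_film(film, n, xlim, ylim)
  d_top <- closest_distance(coords, film$top, mode = mode)
  d_bottom <- closest_distance(coords, film$bottom, mode = mode)
  pp <- tibble(x = coords$x, y = coords$y, z = coords$z,
               d_top = d_top, d_bottom = d_bottom,
               d_min = pmin(abs(d_top), abs(d_bottom)))
  structure(list(particles = pp, n_generated = n, expected_count = expected,
                 seed = as.integer(seed), applied_uM = applied_uM,
                 volume_nm3 = volume, count_mode = count_mode),
            class = "null_model_run")
}

# uniform-in-slab sampler; (x, y) where the fits cross are rejected
sample_in_film <- function(film, n, xlim, ylim) {
  out <- tibble(x = numeric(0), y = numeric(0), z = numeric(0))
  if (n == 0) return(out)
  while (nrow(out) < n) {
    m <- n - nrow(out)
    x <- runif(m, xlim[1], xlim[2])
    y <- runif(m, ylim[1], ylim[2])
    zb <- surface_eval(film$bottom, x, y)
    zt <- surface_eval(film$top, x, y)
    ok <- zt > zb
    if (!any(ok)) next
    z <- zb[ok] + runif(sum(ok)) * (zt[ok] - zb[ok])
    out <- dplyr::bind_rows(out, tibble(x = x[ok], y = y[ok], z = z))
  }
  out
}

#' @export
print.null_model_run <- function(x, ...) {
  cat(sprintf(
    "<null_model_run> %d particles (expected %.2f) at %.3g uM in %.3g nm^3, seed %d\n",
    x$n_generated, x$expected_count, x$applied_uM, x$volume_nm3, x$seed))
  invisible(x)
}

#' Compare a null-model run with an observed partition
#'
#' Bins the per-particle distance to the nearer interface for both the
#' modelled and the observed particles, normalizes counts to densities, and
#' reports the maximum absolute difference between the two empirical CDFs —
#' overall, and restricted to distances beyond a threshold (the
#' "away from the interface" regime where ideal behaviour is expected to
#' match observation even when the interface itself is crowded).
#'
#' @param null A [simulate_null()] result.
#' @param observed An `awi_partition`.
#' @param bin_width_nm Histogram bin width in nm (> 0).
#' @param restrict_above_nm Distance threshold for the restricted statistic
#'   (default 10 nm).
#' @return A `null_comparison`: tibble `bins` (`bin_lo`, `bin_hi`,
#'   `density_observed`, `density_model`), `stat_overall`,
#'   `stat_restricted`, and the sample sizes.
#' @export
compare_to_observed <- function(null, observed, bin_width_nm = 5,
                                restrict_above_nm = 10) {
  if (!inherits(null, "null_model_run")) abort("`null` must be a null_model_run.")
  if (!inherits(observed, "awi_partition")) {
    abort("`observed` must be an awi_partition.")
  }
  if (!is.numeric(bin_width_nm) || bin_width_nm <= 0) {
    abort("`bin_width_nm` must be positive.")
  }
  d_model <- null$particles$d_min
  d_obs <- pmin(abs(observed$particles$d_top), abs(observed$particles$d_bottom))
  if (length(d_model) == 0 || length(d_obs) == 0) {
    abort("both the model run and the observed partition must be non-empty.")
  }
  top <- max(d_model, d_obs, bin_width_nm)
  breaks <- seq(0, top + bin_width_nm, by = bin_width_nm)
  h_obs <- graphics::hist(d_obs, breaks = breaks, plot = FALSE)$counts
  h_mod <- graphics::hist(d_model, breaks = breaks, plot = FALSE)$counts
  bins <- tibble(
    bin_lo = head(breaks, -1), bin_hi = breaks[-1],
    count_observed = h_obs, count_model = h_mod,
    density_observed = h_obs / (length(d_obs) * bin_width_nm),
    density_model = h_mod / (length(d_model) * bin_width_nm)
  )
  structure(list(
    bins = bins,
    stat_overall = max_cdf_diff(d_obs, d_model),
    stat_restricted = max_cdf_diff(d_obs[d_obs > restrict_above_nm],
                                   d_model[d_model > restrict_above_nm]),
    restrict_above_nm = restrict_above_nm,
    n_observed = length(d_obs), n_model = length(d_model)
  ), class = "null_comparison")
}

# two-sample max |ECDF difference| (Kolmogorov-Smirnov distance)
max_cdf_diff <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf(
    "<null_comparison> max |CDF diff| %.3f overall, %.3f beyond %g nm (n_obs %d, n_model %d)\n",
    x$stat_overall, x$stat_restricted, x$restrict_above_nm,
    x$n_observed, x$n_model))
  invisible(x)
}
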