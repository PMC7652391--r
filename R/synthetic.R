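#' Specify a synthetic thin film
#'
#' Ground-truth description of a vitrified thin film on a grid hole: two
#' polynomial interfaces bounding a slab in the 20-180 nm thickness regime,
#' an applied concentration setting the expected particle number, a fraction
#' of particles adsorbed to the interfaces (optionally strongly asymmetric
#' between the faces), a bulk-uniform remainder, and optional surface
#' "rafts" — clusters of tens of particles aggregated on one face.
#'
#' @param area_x_nm,area_y_nm Analysis area in nm.
#' @param thickness_nm Nominal film thickness in nm (> 0; typical 20-180).
#' @param applied_uM Applied solution concentration in uM.
#' @param p_bound Fraction of particles adsorbed at the interfaces, in
#'   \[0, 1\].
#' @param top_share Fraction of adsorbed particles on the top face, in
#'   \[0, 1\].
#' @param jitter_nm SD of the inward half-Gaussian positional jitter of
#'   adsorbed particles (default 2 nm: particle centers of finite-size
#'   complexes sit roughly one radius inside the interface).
#' @param top_coeffs,bottom_coeffs Optional surface coefficient vectors
#'   (`c0, cx, cy[, cxx, cxy, cyy]`); defaults are a flat bottom at z = 0
#'   and a flat top at `thickness_nm`.
#' @param raft_spec Optional list: `n_rafts`, `size_range` (integer pair,
#'   e.g. `c(10, 50)`), `radius_nm`, `surface` (`"top"`/`"bottom"`).
#' @return A `film_spec`.
#' @export
film_spec <- function(area_x_nm = 1000, area_y_nm = 1000, thickness_nm = 100,
                      applied_uM = 1, p_bound = 0, top_share = 0.5,
                      jitter_nm = 2, top_coeffs = NULL, bottom_coeffs = NULL,
                      raft_spec = NULL) {
  if (thickness_nm <= 0) abort("`thickness_nm` must be positive.")
  if (p_bound < 0 || p_bound > 1) abort("`p_bound` must be in [0, 1].")
  if (top_share < 0 || top_share > 1) abort("`top_share` must be in [0, 1].")
  if (applied_uM <= 0) abort("`applied_uM` must be positive.")
  if (jitter_nm < 0) abort("`jitter_nm` must be non-negative.")
  if (is.null(bottom_coeffs)) bottom_coeffs <- c(0, 0, 0)
  if (is.null(top_coeffs)) top_coeffs <- c(thickness_nm, 0, 0)
  if (!is.null(raft_spec)) {
    need <- c("n_rafts", "size_range", "radius_nm")
    if (!all(need %in% names(raft_spec))) {
      abort("`raft_spec` needs n_rafts, size_range and radius_nm.")
    }
    if (any(raft_spec$size_range < 1) || length(raft_spec$size_range) != 2 ||
        raft_spec$size_range[1] > raft_spec$size_range[2]) {
      abort("`raft_spec$size_range` must be a non-decreasing pair of positive integers.")
    }
    raft_spec$surface <- raft_spec$surface %||% "top"
  }
  structure(list(area_x_nm = area_x_nm, area_y_nm = area_y_nm,
                 thickness_nm = thickness_nm, applied_uM = applied_uM,
                 p_bound = p_bound, top_share = top_share,
                 jitter_nm = jitter_nm,
                 top_coeffs = top_coeffs, bottom_coeffs = bottom_coeffs,
                 raft_spec = raft_spec),
            class = "film_spec")
}

#' Thin film with the exact geometry of a film_spec
#'
#' @param spec A [film_spec()].
#' @param eval_n Quadrature resolution.
#' @return A `thin_film` built from the spec's true surface coefficients.
#' @export
film_from_spec <- function(spec, eval_n = 50) {
  if (!inherits(spec, "film_spec")) abort("`spec` must be a film_spec.")
  film_from_coeffs(spec$top_coeffs, spec$bottom_coeffs,
                   xlim = c(0, spec$area_x_nm), ylim = c(0, spec$area_y_nm),
                   eval_n = eval_n)
}

#' Generate a synthetic thin-film particle set with ground truth
#'
#' The total particle number is Poisson with mean
#' `applied_uM * volume * 6.02214076e-7` (the film volume from the spec's
#' true surfaces). A fraction `p_bound` is adsorbed at the interfaces (split
#' top/bottom by `top_share`, displaced inward by a half-Gaussian of SD
#' `jitter_nm`, clamped inside the film), the remainder is uniform in the
#' slab. Rafts, when specified, add clustered particles on one face with
#' cluster sizes uniform over `size_range` and members within `radius_nm` of
#' the raft center; they count toward the adsorbed pool of that surface.
#'
#' @param spec A [film_spec()].
#' @param seed Integer RNG seed.
#' @param n_override Optional fixed total (bypasses the Poisson draw; rafts
#'   still add on top).
#' @return Tibble with columns `x`, `y`, `z` (nm), `true_label`
#'   (`"top"`/`"bottom"`/`"bulk"`/`"raft"`) and `raft_id` (NA off-raft).
#'   The spec and seed are attached as attributes.
#' @export
generate_film_particles <- function(spec, seed = 1, n_override = NULL) {
  if (!inherits(spec, "film_spec")) abort("`spec` must be a film_spec.")
  film <- film_from_spec(spec)
  volume <- film_volume(film)
  expected <- spec$applied_uM * volume * UM_PER_NM3
  set.seed(as.integer(seed))
  n <- if (!is.null(n_override)) as.integer(n_override) else rpois(1, expected)
  if (expected < 6 && is.null(n_override)) {
    warn(sprintf("expected particle count %.3g is too low for surface fitting.",
                 expected))
  }
  n_bound <- round(spec$p_bound * n)
  n_top <- round(spec$top_share * n_bound)
  n_bottom <- n_bound - n_top
  n_bulk <- n - n_bound

  surf_pts <- function(m, side) {
    if (m == 0) {
      return(tibble(x = numeric(0), y = numeric(0), z = numeric(0)))
    }
    x <- runif(m, 0, spec$area_x_nm)
    y <- runif(m, 0, spec$area_y_nm)
    zt <- surface_eval(film$top, x, y)
    zb <- surface_eval(film$bottom, x, y)
    jit <- abs(rnorm(m, 0, spec$jitter_nm))
    z <- if (side == "top") pmax(zb, zt - jit) else pmin(zt, zb + jit)
    tibble(x = x, y = y, z = z)
  }
  top <- surf_pts(n_top, "top")
  bottom <- surf_pts(n_bottom, "bottom")
  bulk <- sample_in_film(film, n_bulk, c(0, spec$area_x_nm),
                         c(0, spec$area_y_nm))
  out <- dplyr::bind_rows(
    dplyr::mutate(top, true_label = "top"),
    dplyr::mutate(bottom, true_label = "bottom"),
    dplyr::mutate(bulk, true_label = "bulk")
  )
  out$raft_id <- NA_integer_
  rs <- spec$raft_spec
  if (!is.null(rs) && rs$n_rafts > 0) {
    rafts <- purrr::map(seq_len(rs$n_rafts), function(k) {
      size <- sample(seq(rs$size_range[1], rs$size_range[2]), 1)
      cx <- runif(1, 0, spec$area_x_nm)
      cy <- runif(1, 0, spec$area_y_nm)
      # uniform in the disc of radius_nm around the raft center
      r <- rs$radius_nm * sqrt(runif(size))
      a <- runif(size, 0, 2 * pi)
      x <- pmin(pmax(cx + r * cos(a), 0), spec$area_x_nm)
      y <- pmin(pmax(cy + r * sin(a), 0), spec$area_y_nm)
      zt <- surface_eval(film$top, x, y)
      zb <- surface_eval(film$bottom, x, y)
      jit <- abs(rnorm(size, 0, spec$jitter_nm))
      z <- if (rs$surface == "top") pmax(zb, zt - jit) else pmin(zt, zb + jit)
      tibble(x = x, y = y, z = z, true_label = "raft", raft_id = k)
    })
    out <- dplyr::bind_rows(out, dplyr::bind_rows(rafts))
  }
  attr(out, "film_spec") <- spec
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Specify a synthetic orientation set
#'
#' A mixture of a rotationally symmetric "preferred view" component about an
#' axis and a uniform remainder — the pattern produced when particles adsorb
#' to an interface in a favoured pose.
#'
#' @param n Number of particles.
#' @param preferred_fraction Mixture weight of the preferred component, in
#'   \[0, 1\].
#' @param preferred_axis Unit vector (length 3) of the preferred view axis.
#' @param angular_radius_95_deg Dispersion of the preferred component,
#'   stated as the angular radius containing 95% of its views
#'   (convention-free).
#' @param symmetry Point-group label carried with the set.
#' @return An `orient_spec`.
#' @export
orient_spec <- function(n, preferred_fraction = 0, preferred_axis = c(0, 0, 1),
                        angular_radius_95_deg = 15, symmetry = "C1") {
  if (n < 1) abort("`n` must be >= 1.")
  if (preferred_fraction < 0 || preferred_fraction > 1) {
    abort("`preferred_fraction` must be in [0, 1].")
  }
  if (length(preferred_axis) != 3 || sum(preferred_axis^2) == 0) {
    abort("`preferred_axis` must be a non-zero 3-vector.")
  }
  structure(list(n = as.integer(n), preferred_fraction = preferred_fraction,
                 preferred_axis = preferred_axis / sqrt(sum(preferred_axis^2)),
                 angular_radius_95_deg = angular_radius_95_deg,
                 symmetry = symmetry),
            class = "orient_spec")
}

# orthonormal frame with `axis` as third column
axis_frame <- function(axis) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cbind(u, v, axis)
}

#' Generate synthetic Euler-angle assignments
#'
#' Draws view directions from the [orient_spec()] mixture — the preferred
#' component's geodesic offset from the axis is half-Gaussian with SD chosen
#' so 95% of its views fall within `angular_radius_95_deg`; the remainder is
#' uniform on the sphere — and converts them to ZYZ Euler angles with psi
#' uniform in \[-180, 180).
#'
#' @param spec An [orient_spec()].
#' @param seed Integer RNG seed.
#' @return Tibble with `rot`, `tilt`, `psi` (degrees) and the implied
#'   direction columns `dx`, `dy`, `dz`.
#' @export
generate_orientations <- function(spec, seed = 1) {
  if (!inherits(spec, "orient_spec")) abort("`spec` must be an orient_spec.")
  set.seed(as.integer(seed))
  n <- spec$n
  pref <- runif(n) < spec$preferred_fraction
  d <- matrix(NA_real_, n, 3)
  n_u <- sum(!pref)
  if (n_u > 0) {
    zz <- runif(n_u, -1, 1)
    az <- runif(n_u, 0, 2 * pi)
    rr <- sqrt(1 - zz^2)
    d[!pref, ] <- cbind(rr * cos(az), rr * sin(az), zz)
  }
  n_p <- sum(pref)
  if (n_p > 0) {
    s <- deg2rad(spec$angular_radius_95_deg) / stats::qnorm(0.975)
    theta <- pmin(abs(rnorm(n_p, 0, s)), pi)
    az <- runif(n_p, 0, 2 * pi)
    local <- cbind(sin(theta) * cos(az), sin(theta) * sin(az), cos(theta))
    d[pref, ] <- local %*% t(axis_frame(spec$preferred_axis))
  }
  tilt <- rad2deg(acos(pmin(pmax(d[, 3], -1), 1)))
  rot <- rad2deg(atan2(d[, 2], d[, 1]))
  tibble(rot = wrap180(rot), tilt = tilt,
         psi = runif(n, -180, 180),
         dx = d[, 1], dy = d[, 2], dz = d[, 3])
}

#' Write a multi-tomogram synthetic cohort to disk
#'
#' One coordinate file (xyz text, nm) and one ground-truth TSV per film
#' spec, plus a manifest. Byte-identical output for identical specs and
#' seeds.
#'
#' @param specs List of [film_spec()] objects.
#' @param seeds Integer seeds, one per spec.
#' @param dir Output directory (created if needed).
#' @param labels Optional unique tomogram labels; default `tomo_001`, ...
#' @return Manifest tibble (label, coordinate file, truth file, n, seed),
#'   invisibly; also written to `manifest.tsv`.
#' @export
make_cohort <- function(specs, seeds, dir, labels = NULL) {
  if (!is.list(specs) || length(specs) == 0 ||
      !all(vapply(specs, inherits, logical(1), "film_spec"))) {
    abort("`specs` must be a non-empty list of film_spec objects.")
  }
  if (length(seeds) != length(specs)) {
    abort("`seeds` must supply one seed per spec.")
  }
  if (is.null(labels)) labels <- sprintf("tomo_%03d", seq_along(specs))
  if (anyDuplicated(labels)) abort("duplicate tomogram labels.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_along(specs), function(i) {
    pts <- generate_film_particles(specs[[i]], seed = seeds[[i]])
    coord_file <- file.path(dir, paste0(labels[i], ".xyz"))
    truth_file <- file.path(dir, paste0(labels[i], "_truth.tsv"))
    writeLines(sprintf("%.9g %.9g %.9g", pts$x, pts$y, pts$z), coord_file)
    readr::write_tsv(
      tibble(id = seq_len(nrow(pts)), true_label = pts$true_label,
             raft_id = pts$raft_id),
      truth_file)
    tibble(label = labels[i], coords = basename(coord_file),
           truth = basename(truth_file), n = nrow(pts),
           seed = as.integer(seeds[[i]]))
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
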