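#' View direction from ZYZ Euler angles
#'
#' The (rot, tilt) pair of a ZYZ Euler triple defines the particle's view
#' axis on the unit sphere; the in-plane angle psi does not change it and is
#' ignored.
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorized; `psi` accepted
#'   for interface symmetry and ignored).
#' @param transpose If `TRUE`, interpret the angles as the inverse rotation
#'   (for datasets whose refinement package stores the transposed
#'   convention): the direction becomes
#'   `(-sin(tilt) cos(psi), sin(tilt) sin(psi), cos(tilt))`.
#' @return Tibble of unit vectors `dx`, `dy`, `dz`.
#' @examples
#' euler_to_direction(0, 0)        # (0, 0, 1)
#' euler_to_direction(90, 90, 42)  # (0, 1, 0)
#' @export
euler_to_direction <- function(rot, tilt, psi = 0, transpose = FALSE) {
  if (!all(is.finite(rot)) || !all(is.finite(tilt))) {
    abort("Euler angles must be finite.")
  }
  ang <- canonicalize_euler(rot, tilt, psi)
  t <- deg2rad(ang$tilt)
  if (transpose) {
    p <- deg2rad(ang$psi)
    d <- cbind(-sin(t) * cos(p), sin(t) * sin(p), cos(t))
  } else {
    r <- deg2rad(ang$rot)
    d <- cbind(sin(t) * cos(r), sin(t) * sin(r), cos(t))
  }
  tibble(dx = d[, 1], dy = d[, 2], dz = d[, 3])
}

dir_matrix <- function(directions) {
  if (is.matrix(directions) && ncol(directions) == 3) return(unname(directions))
  if (is.data.frame(directions) &&
      all(c("dx", "dy", "dz") %in% names(directions))) {
    return(unname(cbind(directions$dx, directions$dy, directions$dz)))
  }
  abort("`directions` must be a matrix or data frame of unit vectors (dx, dy, dz).")
}

#' Rotation matrices of a point group
#'
#' @param group `"C1"`, `"Cn"` for any n (e.g. `"C7"`), or `"O"` (the
#'   octahedral rotation group, order 24).
#' @return List of 3x3 rotation matrices.
#' @export
symmetry_rotations <- function(group) {
  if (!is.character(group) || length(group) != 1) {
    abort("`group` must be a single point-group label.")
  }
  if (grepl("^[Cc][0-9]+$", group)) {
    n <- as.integer(sub("^[Cc]", "", group))
    if (n < 1) abort(sprintf("unknown point group: %s", group))
    return(lapply(seq_len(n) - 1, function(k) {
      a <- 2 * pi * k / n
      matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
             3, 3, byrow = TRUE)
    }))
  }
  if (toupper(group) == "O") {
    # all signed permutation matrices with determinant +1
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    out <- list()
    for (p in perms) {
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
        m <- matrix(0, 3, 3)
        m[1, p[1]] <- s1; m[2, p[2]] <- s2; m[3, p[3]] <- s3
        if (abs(det(m) - 1) < 1e-12) out[[length(out) + 1]] <- m
      }
    }
    return(out)
  }
  abort(sprintf("unknown point group: %s", group))
}

#' Replicate view directions under a point group
#'
#' Each direction is mapped through every rotation of the group about the
#' symmetry frame (Cn: n rotations about z; O: the 24 octahedral rotations).
#' C1 returns the input unchanged.
#'
#' @param directions Tibble/matrix of unit vectors (`dx`, `dy`, `dz`).
#' @param group Point-group label (`"C1"`, `"Cn"`, `"O"`).
#' @return Tibble of expanded directions, `length(group) * n` rows, input
#'   order preserved within each rotation block.
#' @export
expand_symmetry <- function(directions, group = "C1") {
  d <- dir_matrix(directions)
  rots <- symmetry_rotations(group)
  out <- do.call(rbind, lapply(rots, function(R) d %*% t(R)))
  tibble(dx = out[, 1], dy = out[, 2], dz = out[, 3])
}

#' Gaussian kernel sum on the sphere
#'
#' Unnormalized spherical kernel density: for each query direction q,
#' `sum_i exp(-theta(q, d_i)^2 / (2 sigma^2))` with theta the geodesic angle
#' and sigma the bandwidth in radians. This is the quantity
#' [spherical_kde()] normalizes into a PDF; it is exposed for evaluating the
#' density at arbitrary directions (e.g. symmetry-equivariance checks).
#'
#' @param directions Data directions (tibble/matrix of unit vectors).
#' @param query Query directions (same formats).
#' @param bandwidth_deg Kernel bandwidth in degrees (> 0).
#' @return Numeric vector, one kernel sum per query direction.
#' @export
kde_kernel_sum <- function(directions, query, bandwidth_deg = 10) {
  if (!is.numeric(bandwidth_deg) || bandwidth_deg <= 0) {
    abort("`bandwidth_deg` must be positive.")
  }
  d <- dir_matrix(directions)
  q <- dir_matrix(query)
  sigma <- deg2rad(bandwidth_deg)
  out <- numeric(nrow(q))
  # chunk the query x data cosine matrix to bound memory
  chunk <- max(1L, as.integer(2e7 / max(1, nrow(d))))
  for (s in seq(1, nrow(q), by = chunk)) {
    idx <- s:min(s + chunk - 1, nrow(q))
    cosang <- q[idx, , drop = FALSE] %*% t(d)
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    theta <- acos(cosang)
    out[idx] <- rowSums(exp(-theta^2 / (2 * sigma^2)))
  }
  out
}

# area-weighted latitude-longitude grid; area element exact per cell
sphere_grid <- function(res_deg) {
  lat <- seq(-90 + res_deg / 2, 90 - res_deg / 2, by = res_deg)
  lon <- seq(-180 + res_deg / 2, 180 - res_deg / 2, by = res_deg)
  g <- expand.grid(lon_deg = lon, lat_deg = lat)
  band <- deg2rad(res_deg)
  g$area_sr <- band * (sin(deg2rad(g$lat_deg) + band / 2) -
                         sin(deg2rad(g$lat_deg) - band / 2))
  as_tibble(g)
}

lonlat_to_xyz <- function(lon_deg, lat_deg) {
  lon <- deg2rad(lon_deg)
  lat <- deg2rad(lat_deg)
  cbind(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
}

#' Orientation probability density on the sphere
#'
#' Kernel density estimate of the view-direction distribution with a
#' Gaussian kernel in the geodesic angle (default bandwidth 10 degrees,
#' chosen wider than typical angular assignment accuracy so maps are not
#' over-interpreted), evaluated on an area-weighted latitude-longitude grid
#' and renormalized numerically so the PDF integrates to 1 over the sphere.
#'
#' @param directions Unit vectors (`dx`, `dy`, `dz`), e.g. from
#'   [euler_to_direction()], or a data frame with `rot`/`tilt` columns.
#' @param bandwidth_deg Kernel bandwidth in degrees (default 10).
#' @param grid_res_deg Grid resolution in degrees (default 1).
#' @param symmetry Point-group label recorded with the map; when
#'   `expand = TRUE` the directions are replicated under it first. Default
#'   is no expansion, so e.g. a C7 map occupies one-seventh of the sphere.
#' @param expand Apply [expand_symmetry()] before estimation.
#' @return An `orientation_pdf`: tibble `grid` (`lon_deg`, `lat_deg`,
#'   `area_sr`, `pdf_sr`), plus `bandwidth_deg`, `symmetry`, `n_particles`
#'   and the (possibly expanded) `directions` used.
#' @export
spherical_kde <- function(directions, bandwidth_deg = 10, grid_res_deg = 1,
                          symmetry = "C1", expand = FALSE) {
  if (is.data.frame(directions) &&
      all(c("rot", "tilt") %in% names(directions))) {
    directions <- euler_to_direction(directions$rot, directions$tilt)
  }
  d <- dir_matrix(directions)
  if (nrow(d) < 1) abort("need at least one direction.")
  n_in <- nrow(d)
  if (expand) d <- dir_matrix(expand_symmetry(d, symmetry))
  grid <- sphere_grid(grid_res_deg)
  dens <- kde_kernel_sum(d, lonlat_to_xyz(grid$lon_deg, grid$lat_deg),
                         bandwidth_deg)
  grid$pdf_sr <- dens / sum(dens * grid$area_sr)
  structure(list(grid = grid, bandwidth_deg = bandwidth_deg,
                 grid_res_deg = grid_res_deg, symmetry = symmetry,
                 expanded = expand, n_particles = n_in,
                 directions = tibble(dx = d[, 1], dy = d[, 2], dz = d[, 3])),
            class = "orientation_pdf")
}

#' @export
print.orientation_pdf <- function(x, ...) {
  cat(sprintf(
    "<orientation_pdf> %d particles, bandwidth %g deg, %g deg grid, %s%s\n",
    x$n_particles, x$bandwidth_deg, x$grid_res_deg, x$symmetry,
    if (x$expanded) " (expanded)" else ""))
  cat(sprintf("  max density %.4g sr^-1 (uniform = %.4g)\n",
              max(x$grid$pdf_sr), 1 / (4 * pi)))
  invisible(x)
}

#' Mollweide projection of longitude/latitude
#'
#' Equal-area projection of the sphere onto a 2R x sqrt(2)R... ellipse of
#' semi-axes 2R (x) and sqrt(2) R (y). The auxiliary angle solves
#' `2 theta + sin(2 theta) = pi sin(lat)` by Newton iteration.
#'
#' @param lon_deg,lat_deg Coordinates in degrees (vectorized).
#' @param R Projection radius (default 1).
#' @return Tibble with projected `x`, `y`.
#' @examples
#' mollweide_xy(0, 0)    # (0, 0)
#' mollweide_xy(0, 90)   # (0, sqrt(2))
#' @export
mollweide_xy <- function(lon_deg, lat_deg, R = 1) {
  lon <- deg2rad(wrap180(lon_deg))
  lat <- deg2rad(lat_deg)
  theta <- lat
  for (it in 1:50) {
    delta <- -(2 * theta + sin(2 * theta) - pi * sin(lat)) /
      (2 + 2 * cos(2 * theta))
    delta[!is.finite(delta)] <- 0  # poles: already converged
    theta <- theta + delta
    if (max(abs(delta)) < 1e-13) break
  }
  pole <- abs(abs(lat) - pi / 2) < 1e-12
  theta[pole] <- sign(lat[pole]) * pi / 2
  tibble(x = 2 * sqrt(2) / pi * R * lon * cos(theta),
         y = sqrt(2) * R * sin(theta))
}

#' Write (and optionally plot) a Mollweide orientation map
#'
#' Writes the gridded density table — longitude, latitude, PDF value and the
#' projected Mollweide x/y — as tab-separated text (the machine-checkable
#' artifact), and optionally saves a raster rendering.
#'
#' @param pdf An `orientation_pdf`.
#' @param table_path Output TSV path.
#' @param image_path Optional PNG path rendered with ggplot2.
#' @param width,height Image size in inches.
#' @return The written table, invisibly.
#' @export
render_mollweide <- function(pdf, table_path, image_path = NULL,
                             width = 7, height = 4) {
  if (!inherits(pdf, "orientation_pdf")) {
    abort("`pdf` must be an orientation_pdf.")
  }
  xy <- mollweide_xy(pdf$grid$lon_deg, pdf$grid$lat_deg)
  tab <- dplyr::bind_cols(
    pdf$grid[c("lon_deg", "lat_deg", "pdf_sr")], xy)
  tryCatch(readr::write_tsv(tab, table_path),
           error = function(e) abort(sprintf("cannot write %s: %s", table_path,
                                             conditionMessage(e))))
  if (!is.null(image_path)) {
    ggplot2::ggsave(image_path, ggplot2::autoplot(pdf),
                    width = width, height = height, dpi = 150)
  }
  invisible(tab)
}
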