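#' Build a patch grid over the particle cloud
#'
#' Divides the x/y bounding rectangle of the particle cloud into `nx * ny`
#' patches. In `"auto"` mode the total patch count is the largest value not
#' exceeding 16 that keeps the expected occupancy at two or more particles
#' per patch, and the split between nx and ny follows the aspect ratio of
#' the bounds as closely as the factorization allows.
#'
#' @param particles Data frame with columns `x`, `y`, `z` (nm).
#' @param n_patches Integer in \[4, 16\], or `"auto"`.
#' @return A `patch_grid` object (fields `nx`, `ny`, `xlim`, `ylim`).
#' @examples
#' pts <- tibble::tibble(x = runif(400, 0, 1000), y = runif(400, 0, 1000),
#'                       z = runif(400, 0, 100))
#' make_patch_grid(pts)  # 4 x 4
#' @export
make_patch_grid <- function(particles, n_patches = "auto") {
  check_xyz(particles)
  n <- nrow(particles)
  if (n < 4) abort("insufficient data: need at least 4 particles for a patch grid.")
  xlim <- range(particles$x)
  ylim <- range(particles$y)
  # degenerate (zero-width) bounds still tile; aspect falls back to 1
  wx <- diff(xlim)
  wy <- diff(ylim)
  aspect <- if (wx > 0 && wy > 0) wx / wy else 1
  if (identical(n_patches, "auto")) {
    total <- max(2L, min(16L, as.integer(floor(n / 2))))
  } else {
    if (!is.numeric(n_patches) || length(n_patches) != 1 ||
        n_patches != round(n_patches) || n_patches < 4 || n_patches > 16) {
      abort("`n_patches` must be an integer in [4, 16] or \"auto\".")
    }
    total <- as.integer(n_patches)
  }
  # factor pair of `total` closest to the bounds' aspect ratio
  divs <- which(total %% seq_len(total) == 0)
  nx <- divs[which.min(abs(log(divs^2 / total) - log(aspect)))]
  ny <- total %/% nx
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 xlim = xlim, ylim = ylim),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d x %d over x [%.4g, %.4g], y [%.4g, %.4g] nm\n",
              x$nx, x$ny, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2]))
  invisible(x)
}

patch_index <- function(particles, grid) {
  ix <- findInterval(particles$x, seq(grid$xlim[1], grid$xlim[2],
                                      length.out = grid$nx + 1),
                     rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(particles$y, seq(grid$ylim[1], grid$ylim[2],
                                      length.out = grid$ny + 1),
                     rightmost.closed = TRUE, all.inside = TRUE)
  (iy - 1L) * grid$nx + ix
}

#' Select extremal particles per patch
#'
#' From each non-empty patch, the particle at maximum z goes into the top
#' support set and the particle at minimum z into the bottom support set
#' (a single-occupancy patch contributes its particle to both). Ties in z
#' are broken toward the lowest input row index.
#'
#' @param particles Data frame with columns `x`, `y`, `z` (nm).
#' @param grid A [make_patch_grid()] result built from the same cloud.
#' @return A list with tibbles `top` and `bottom` (columns x, y, z, row).
#' @export
select_extremal <- function(particles, grid) {
  check_xyz(particles)
  if (nrow(particles) == 0) abort("insufficient data: no particles.")
  df <- tibble(x = particles$x, y = particles$y, z = particles$z,
               row = seq_len(nrow(particles)),
               patch = patch_index(particles, grid))
  pick <- df |>
    dplyr::group_by(.data$patch) |>
    dplyr::summarise(
      top = .data$row[which.max(.data$z)],
      bottom = .data$row[which.min(.data$z)],
      .groups = "drop"
    )
  list(
    top = df[pick$top, c("x", "y", "z", "row")],
    bottom = df[pick$bottom, c("x", "y", "z", "row")]
  )
}

poly_design <- function(x, y, order) {
  if (order == 1) cbind(1, x, y)
  else cbind(1, x, y, x^2, x * y, y^2)
}

coef_names <- function(order) {
  if (order == 1) c("c0", "cx", "cy") else c("c0", "cx", "cy", "cxx", "cxy", "cyy")
}

fit_one_order <- function(points, order) {
  X <- poly_design(points$x, points$y, order)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort(sprintf(
      "degenerate geometry: support (x, y) positions do not determine an order-%d surface.",
      order))
  }
  cf <- qr.coef(qrX, points$z)
  res <- points$z - as.vector(X %*% cf)
  list(coeffs = setNames(as.vector(cf), coef_names(order)),
       rms = sqrt(mean(res^2)))
}

#' Fit a polynomial surface z = f(x, y) to support points
#'
#' Least-squares fit of a plane (order 1) or full quadratic (order 2).
#' With `order = "auto"` a plane is used unless there are at least 9 support
#' points and the quadratic reduces the rms residual by more than 20%.
#'
#' @param points Data frame with columns `x`, `y`, `z` (nm); the support set.
#' @param order 1, 2, or `"auto"`.
#' @param side `"top"` or `"bottom"`: which interface of the film this
#'   surface is, fixing the sign convention of [closest_distance()].
#' @return A `fitted_surface` with coefficients
#'   `(c0, cx, cy[, cxx, cxy, cyy])` of
#'   `z = c0 + cx x + cy y + cxx x^2 + cxy xy + cyy y^2`, the support points
#'   and the rms residual in nm.
#' @export
fit_surface <- function(points, order = "auto", side = c("top", "bottom")) {
  check_xyz(points, "points")
  side <- match.arg(side)
  n <- nrow(points)
  if (identical(order, "auto")) {
    if (n < 3) abort("insufficient data: need >= 3 support points.")
    f1 <- fit_one_order(points, 1)
    use2 <- FALSE
    if (n >= 9) {
      f2 <- tryCatch(fit_one_order(points, 2), error = function(e) NULL)
      if (!is.null(f2) && f2$rms < 0.8 * f1$rms) use2 <- TRUE
    }
    fit <- if (use2) f2 else f1
    order <- if (use2) 2L else 1L
  } else {
    if (!order %in% c(1, 2)) abort("`order` must be 1, 2 or \"auto\".")
    order <- as.integer(order)
    need <- if (order == 1) 3 else 6
    if (n < need) {
      abort(sprintf("insufficient data: order %d needs >= %d support points, got %d.",
                    order, need, n))
    }
    fit <- fit_one_order(points, order)
  }
  structure(list(order = order, coeffs = fit$coeffs, side = side,
                 support_points = as_tibble(points[c("x", "y", "z")]),
                 rms_residual = fit$rms),
            class = "fitted_surface")
}

#' Construct a fitted_surface directly from coefficients
#'
#' Used by the synthetic generator and the null model to build films with
#' exactly known geometry.
#'
#' @param coeffs Numeric vector of length 3 (order 1) or 6 (order 2):
#'   `(c0, cx, cy[, cxx, cxy, cyy])`.
#' @param side `"top"` or `"bottom"`.
#' @return A `fitted_surface` with zero residual and no support points.
#' @export
surface_from_coeffs <- function(coeffs, side = c("top", "bottom")) {
  side <- match.arg(side)
  if (!length(coeffs) %in% c(3, 6) || !all(is.finite(coeffs))) {
    abort("`coeffs` must be 3 or 6 finite numbers.")
  }
  order <- if (length(coeffs) == 3) 1L else 2L
  structure(list(order = order,
                 coeffs = setNames(as.numeric(coeffs), coef_names(order)),
                 side = side,
                 support_points = tibble(x = numeric(), y = numeric(),
                                         z = numeric()),
                 rms_residual = 0),
            class = "fitted_surface")
}

#' Evaluate a fitted surface at (x, y)
#'
#' @param surface A `fitted_surface`.
#' @param x,y Coordinates in nm (recycled to common length).
#' @return Surface height z in nm.
#' @export
surface_eval <- function(surface, x, y) {
  cf <- surface$coeffs
  z <- cf[["c0"]] + cf[["cx"]] * x + cf[["cy"]] * y
  if (surface$order == 2) {
    z <- z + cf[["cxx"]] * x^2 + cf[["cxy"]] * x * y + cf[["cyy"]] * y^2
  }
  z
}

#' @export
print.fitted_surface <- function(x, ...) {
  cat(sprintf("<fitted_surface> %s, order %d, rms residual %.4g nm, %d support points\n",
              x$side, x$order, x$rms_residual, nrow(x$support_points)))
  print(round(x$coeffs, 6))
  invisible(x)
}

#' Signed closest distance from points to a fitted surface
#'
#' The magnitude is the minimum Euclidean distance from each point to the
#' surface sheet `z = f(x, y)` (closed form for planes; 2-D minimization of
#' the squared distance, started from the point's own (x, y), for quadrics).
#' The sign is positive when the point lies on the film side of the surface
#' (below a top surface, above a bottom surface) and negative outside.
#' `mode = "vertical"` returns the signed vertical gap instead.
#'
#' @param points Data frame with columns `x`, `y`, `z` (nm), or a numeric
#'   length-3 vector for a single point.
#' @param surface A `fitted_surface` (its `side` fixes the sign).
#' @param mode `"euclidean"` (default) or `"vertical"`.
#' @return Numeric vector of signed distances in nm.
#' @examples
#' s <- surface_from_coeffs(c(0, 0, 0), side = "bottom")
#' closest_distance(c(0, 0, 5), s)  # +5
#' @export
closest_distance <- function(points, surface,
                             mode = c("euclidean", "vertical")) {
  mode <- match.arg(mode)
  if (is.numeric(points) && is.null(dim(points))) {
    if (length(points) != 3) abort("a single point must have 3 coordinates.")
    points <- tibble(x = points[1], y = points[2], z = points[3])
  }
  check_xyz(points, "points")
  inside_sign <- if (surface$side == "top") {
    sign_vec(surface_eval(surface, points$x, points$y) - points$z)
  } else {
    sign_vec(points$z - surface_eval(surface, points$x, points$y))
  }
  vgap <- abs(points$z - surface_eval(surface, points$x, points$y))
  if (mode == "vertical") return(inside_sign * vgap)
  if (surface$order == 1) {
    cf <- surface$coeffs
    denom <- sqrt(1 + cf[["cx"]]^2 + cf[["cy"]]^2)
    return(inside_sign * vgap / denom)
  }
  # order 2: minimize (u-x)^2 + (v-y)^2 + (f(u,v) - z)^2 per point
  cf <- surface$coeffs
  d <- vapply(seq_len(nrow(points)), function(i) {
    p <- c(points$x[i], points$y[i], points$z[i])
    obj <- function(uv) {
      fz <- cf[["c0"]] + cf[["cx"]] * uv[1] + cf[["cy"]] * uv[2] +
        cf[["cxx"]] * uv[1]^2 + cf[["cxy"]] * uv[1] * uv[2] +
        cf[["cyy"]] * uv[2]^2
      (uv[1] - p[1])^2 + (uv[2] - p[2])^2 + (fz - p[3])^2
    }
    grad <- function(uv) {
      fz <- cf[["c0"]] + cf[["cx"]] * uv[1] + cf[["cy"]] * uv[2] +
        cf[["cxx"]] * uv[1]^2 + cf[["cxy"]] * uv[1] * uv[2] +
        cf[["cyy"]] * uv[2]^2
      dfu <- cf[["cx"]] + 2 * cf[["cxx"]] * uv[1] + cf[["cxy"]] * uv[2]
      dfv <- cf[["cy"]] + 2 * cf[["cyy"]] * uv[2] + cf[["cxy"]] * uv[1]
      c(2 * (uv[1] - p[1]) + 2 * (fz - p[3]) * dfu,
        2 * (uv[2] - p[2]) + 2 * (fz - p[3]) * dfv)
    }
    opt <- optim(p[1:2], obj, gr = grad, method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500))
    sqrt(max(opt$value, 0))
  }, numeric(1))
  inside_sign * d
}

# sign() that treats points exactly on the surface as inside
sign_vec <- function(x) ifelse(x >= 0, 1, -1)

#' Locate both air-water interfaces of a thin film
#'
#' Runs the full surface pipeline: patch grid over the particle cloud,
#' per-patch z-extremal selection, polynomial fit of the top surface to the
#' maxima and the bottom surface to the minima, then the mean film thickness
#' by quadrature of top - bottom over the bounds. Each face's polynomial
#' order is chosen independently in `"auto"` mode.
#'
#' @param particles Data frame with columns `x`, `y`, `z` (nm).
#' @param n_patches Passed to [make_patch_grid()].
#' @param order Passed to [fit_surface()] for both faces.
#' @param eval_n Evaluation grid resolution for the thickness quadrature and
#'   crossing check (default 50, i.e. 50 x 50 cells).
#' @return A `thin_film` with fields `top`, `bottom` (fitted surfaces),
#'   `grid`, `bounds` and `mean_thickness_nm`.
#' @export
build_film <- function(particles, n_patches = "auto", order = "auto",
                       eval_n = 50) {
  check_xyz(particles)
  if (nrow(particles) < 6) {
    abort("insufficient data: need >= 6 particles to locate both interfaces.")
  }
  grid <- make_patch_grid(particles, n_patches)
  ext <- select_extremal(particles, grid)
  top <- fit_surface(ext$top, order = order, side = "top")
  bottom <- fit_surface(ext$bottom, order = order, side = "bottom")
  film_from_surfaces(top, bottom, grid, eval_n = eval_n)
}

film_from_surfaces <- function(top, bottom, grid, eval_n = 50) {
  xs <- seq(grid$xlim[1], grid$xlim[2], length.out = eval_n)
  ys <- seq(grid$ylim[1], grid$ylim[2], length.out = eval_n)
  g <- expand.grid(x = xs, y = ys)
  thick <- surface_eval(top, g$x, g$y) - surface_eval(bottom, g$x, g$y)
  crossing <- mean(thick < 0)
  if (crossing > 0.01) {
    abort(sprintf(
      "inconsistent film: top surface below bottom on %.1f%% of the evaluation grid.",
      100 * crossing))
  }
  mean_thick <- mean(thick)
  if (!is.finite(mean_thick) || mean_thick <= 0) {
    abort("zero-thickness film: the two interfaces coincide.")
  }
  structure(list(top = top, bottom = bottom, grid = grid,
                 bounds = list(xlim = grid$xlim, ylim = grid$ylim),
                 mean_thickness_nm = mean_thick,
                 eval_n = eval_n),
            class = "thin_film")
}

#' Construct a thin film from known surface coefficients
#'
#' Builds a `thin_film` with exactly specified geometry, bypassing the fit.
#' Used to generate synthetic data, to run the null model on a known slab,
#' and in parameter-recovery tests.
#'
#' @param top_coeffs,bottom_coeffs Coefficient vectors
#'   (`c0, cx, cy[, cxx, cxy, cyy]`) of the two interfaces.
#' @param xlim,ylim Analysis bounds in nm.
#' @param eval_n Thickness quadrature resolution.
#' @return A `thin_film`.
#' @examples
#' film_from_coeffs(c(100, 0, 0), c(0, 0, 0), xlim = c(0, 1000),
#'                  ylim = c(0, 1000))
#' @export
film_from_coeffs <- function(top_coeffs, bottom_coeffs, xlim, ylim,
                             eval_n = 50) {
  grid <- structure(list(nx = 1L, ny = 1L, xlim = as.numeric(xlim),
                         ylim = as.numeric(ylim)), class = "patch_grid")
  film_from_surfaces(surface_from_coeffs(top_coeffs, "top"),
                     surface_from_coeffs(bottom_coeffs, "bottom"),
                     grid, eval_n = eval_n)
}

#' @export
print.thin_film <- function(x, ...) {
  cat(sprintf("<thin_film> mean thickness %.2f nm over x [%.4g, %.4g], y [%.4g, %.4g] nm\n",
              x$mean_thickness_nm, x$bounds$xlim[1], x$bounds$xlim[2],
              x$bounds$ylim[1], x$bounds$ylim[2]))
  cat(sprintf("  top:    order %d, rms %.3g nm\n", x$top$order, x$top$rms_residual))
  cat(sprintf("  bottom: order %d, rms %.3g nm\n", x$bottom$order, x$bottom$rms_residual))
  invisible(x)
}
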