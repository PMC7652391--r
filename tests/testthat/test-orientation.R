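test_that("Euler angles map to view directions, independent of psi", {
  expect_equal(unlist(euler_to_direction(0, 0, 123)), c(dx = 0, dy = 0, dz = 1))
  d <- euler_to_direction(90, 90, 7)
  expect_equal(unlist(d), c(dx = 0, dy = 1, dz = 0), tolerance = 1e-12)
  a <- euler_to_direction(30, 60, 0)
  b <- euler_to_direction(30, 60, 117)
  expect_equal(a, b)
  # canonicalization: tilt beyond 180 folds onto the same direction
  expect_equal(euler_to_direction(30, 200), euler_to_direction(210, 160),
               tolerance = 1e-12)
  expect_error(euler_to_direction(NA, 10), "finite")
  # all outputs are unit vectors
  set.seed(3)
  dd <- euler_to_direction(runif(100, -720, 720), runif(100, -360, 720))
  expect_equal(dd$dx^2 + dd$dy^2 + dd$dz^2, rep(1, 100), tolerance = 1e-9)
})

test_that("point-group expansion replicates directions correctly", {
  d <- euler_to_direction(25, 70)
  expect_equal(expand_symmetry(d, "C1"), d)
  e7 <- expand_symmetry(d, "C7")
  expect_equal(nrow(e7), 7)
  expect_equal(e7$dz, rep(d$dz, 7), tolerance = 1e-12)  # z preserved by Cn
  expect_equal(e7$dx^2 + e7$dy^2 + e7$dz^2, rep(1, 7), tolerance = 1e-12)
  # the 7 images are distinct rotations about z
  az <- sort(atan2(e7$dy, e7$dx))
  expect_equal(diff(az), rep(2 * pi / 7, 6), tolerance = 1e-9)
  eo <- expand_symmetry(d, "O")
  expect_equal(nrow(eo), 24)
  expect_equal(length(symmetry_rotations("O")), 24)
  # every octahedral matrix is a proper rotation
  dets <- vapply(symmetry_rotations("O"), det, numeric(1))
  expect_equal(dets, rep(1, 24), tolerance = 1e-12)
  expect_error(expand_symmetry(d, "icosahedral"), "unknown point group")
})

test_that("the KDE normalizes to one with its maximum at the data", {
  d <- euler_to_direction(40, 55)
  pdf <- spherical_kde(d, grid_res_deg = 2)
  expect_equal(sum(pdf$grid$pdf_sr * pdf$grid$area_sr), 1, tolerance = 1e-3)
  expect_true(all(pdf$grid$pdf_sr >= 0))
  peak <- pdf$grid[which.max(pdf$grid$pdf_sr), ]
  peak_dir <- c(cos(peak$lat_deg * pi / 180) * cos(peak$lon_deg * pi / 180),
                cos(peak$lat_deg * pi / 180) * sin(peak$lon_deg * pi / 180),
                sin(peak$lat_deg * pi / 180))
  ang <- acos(sum(peak_dir * unlist(d))) * 180 / pi
  expect_lt(ang, 2 * sqrt(2))  # within one grid cell of the lone direction
  # two antipodal directions give two equal maxima
  anti <- tibble::tibble(dx = c(0, 0), dy = c(0, 0), dz = c(1, -1))
  p2 <- spherical_kde(anti, grid_res_deg = 2)
  top_cells <- p2$grid[p2$grid$pdf_sr > 0.999 * max(p2$grid$pdf_sr), ]
  expect_setequal(sign(top_cells$lat_deg), c(-1, 1))
  expect_error(spherical_kde(d, bandwidth_deg = 0), "positive")
})

test_that("Euler-angle data frames are accepted directly", {
  ang <- tibble::tibble(rot = c(0, 90), tilt = c(0, 90), psi = 0)
  pdf <- spherical_kde(ang, grid_res_deg = 5)
  expect_s3_class(pdf, "orientation_pdf")
  expect_equal(pdf$n_particles, 2)
})

test_that("the uniform limit is flat at 1/(4 pi)", {
  set.seed(5)
  z <- runif(4000, -1, 1)
  az <- runif(4000, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  dirs <- tibble::tibble(dx = r * cos(az), dy = r * sin(az), dz = z)
  pdf <- spherical_kde(dirs, grid_res_deg = 4)
  rel_dev <- abs(pdf$grid$pdf_sr - 1 / (4 * pi)) / (1 / (4 * pi))
  # KDE sampling theory: pointwise relative sd ~ 1/(sigma sqrt(n)) with
  # sigma the bandwidth in radians; the sphere holds ~4pi/(2 pi sigma^2)
  # kernel-independent patches, so the max sits near 3 of those sds
  sigma <- 10 * pi / 180
  sd_rel <- 1 / (sigma * sqrt(4000))
  expect_lt(mean(rel_dev), 2 * sd_rel)
  expect_lt(max(rel_dev), 6 * sd_rel)
})

test_that("Cn expansion makes the density invariant under the group rotation", {
  set.seed(6)
  spec <- orient_spec(300, preferred_fraction = 0.8,
                      preferred_axis = c(0.5, 0.3, 0.81),
                      angular_radius_95_deg = 20)
  dirs <- generate_orientations(spec, seed = 7)[, c("dx", "dy", "dz")]
  expanded <- expand_symmetry(dirs, "C7")
  # evaluate the kernel sum at arbitrary queries and their 2pi/7 rotations
  q <- generate_orientations(orient_spec(200), seed = 8)[, c("dx", "dy", "dz")]
  a <- 2 * pi / 7
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  qr <- as.matrix(q) %*% t(R)
  f <- kde_kernel_sum(expanded, q)
  fr <- kde_kernel_sum(expanded, qr)
  expect_equal(fr, f, tolerance = 1e-8)
})

test_that("smoothing more never raises the peak density", {
  set.seed(9)
  dirs <- generate_orientations(
    orient_spec(400, preferred_fraction = 0.7, angular_radius_95_deg = 12),
    seed = 10)[, c("dx", "dy", "dz")]
  peaks <- vapply(c(5, 10, 20, 40), function(bw) {
    max(spherical_kde(dirs, bandwidth_deg = bw, grid_res_deg = 3)$grid$pdf_sr)
  }, numeric(1))
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("a preferred-orientation mixture concentrates the PDF mass", {
  # 90% preferred with 95% of those views within 15 degrees of the axis: the
  # raw directions put ~89% of their mass within 20 degrees; the 10-degree
  # kernel then relocates part of that just outside (tangent-plane spread
  # sqrt(7.65^2 + 10^2) ~ 12.6 degrees), so the smoothed-density checks are
  # placed at 20 degrees against the uniform baseline and at 30 degrees for
  # the 80% mass bound
  spec <- orient_spec(2000, preferred_fraction = 0.9,
                      preferred_axis = c(0, 0, 1), angular_radius_95_deg = 15)
  tab <- generate_orientations(spec, seed = 11)
  dirs <- tab[, c("dx", "dy", "dz")]
  expect_gte(mean(dirs$dz >= cos(20 * pi / 180)), 0.8)  # data mass itself
  pdf <- spherical_kde(dirs, grid_res_deg = 2)
  ang <- acos(pmin(pmax(sin(pdf$grid$lat_deg * pi / 180), -1), 1))
  mass <- function(radius_deg) {
    keep <- ang <= radius_deg * pi / 180
    sum(pdf$grid$pdf_sr[keep] * pdf$grid$area_sr[keep])
  }
  uniform_cap_20 <- (1 - cos(20 * pi / 180)) / 2
  expect_gte(mass(20), 15 * uniform_cap_20)  # >> uniform: clear signal
  expect_gte(mass(30), 0.8)
})

test_that("Mollweide projection is centred, pole-exact and equal-area", {
  expect_equal(unlist(mollweide_xy(0, 0)), c(x = 0, y = 0))
  expect_equal(mollweide_xy(0, 90)$y, sqrt(2), tolerance = 1e-9)
  expect_equal(mollweide_xy(0, -90)$y, -sqrt(2), tolerance = 1e-9)
  expect_equal(mollweide_xy(123, 90)$x, 0, tolerance = 1e-9)
  # numeric Jacobian oracle on a 5-degree grid: |det J| / cos(lat) constant
  # to 1% (the projection is analytically equal-area)
  h <- 1e-3
  g <- expand.grid(lon = seq(-177.5, 177.5, by = 5),
                   lat = seq(-87.5, 87.5, by = 5))
  xy <- function(dl, dp) mollweide_xy(g$lon + dl, g$lat + dp)
  dx_dlon <- (xy(h, 0)$x - xy(-h, 0)$x) / (2 * h)
  dy_dlon <- (xy(h, 0)$y - xy(-h, 0)$y) / (2 * h)
  dx_dlat <- (xy(0, h)$x - xy(0, -h)$x) / (2 * h)
  dy_dlat <- (xy(0, h)$y - xy(0, -h)$y) / (2 * h)
  detJ <- abs(dx_dlon * dy_dlat - dx_dlat * dy_dlon)
  ratio <- detJ / cos(g$lat * pi / 180)
  expect_lt(max(abs(ratio / mean(ratio) - 1)), 0.01)
})

test_that("render_mollweide writes the gridded table artifact", {
  dirs <- euler_to_direction(c(10, 200), c(40, 80))
  pdf <- spherical_kde(dirs, grid_res_deg = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- render_mollweide(pdf, f)
  expect_true(file.exists(f))
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(back), c("lon_deg", "lat_deg", "pdf_sr", "x", "y"))
  expect_equal(nrow(back), nrow(pdf$grid))
  expect_equal(back$pdf_sr, pdf$grid$pdf_sr, tolerance = 1e-6)
})
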