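test_that("auto patch grids satisfy the two-per-patch occupancy rule", {
  # plenty of particles: the 16-patch cap binds, split 4 x 4 on square bounds
  g <- make_patch_grid(uniform_slab(400, seed = 2))
  expect_equal(c(g$nx, g$ny), c(4L, 4L))
  # 9 particles: brute force over admissible (nx, ny) with expected >= 2
  # per patch allows at most 4 patches -> 2 x 2
  g9 <- make_patch_grid(uniform_slab(9, seed = 3))
  expect_equal(g9$nx * g9$ny, 4L)
  expect_equal(c(g9$nx, g9$ny), c(2L, 2L))
  expect_error(make_patch_grid(uniform_slab(3)), "insufficient")
})

test_that("explicit patch counts follow the bounds' aspect ratio", {
  set.seed(4)
  pts <- tibble::tibble(x = runif(60, 0, 200), y = runif(60, 0, 300),
                        z = runif(60, 0, 50))
  g <- make_patch_grid(pts, n_patches = 6)
  expect_equal(c(g$nx, g$ny), c(2L, 3L))
  wide <- tibble::tibble(x = pts$y, y = pts$x, z = pts$z)
  gw <- make_patch_grid(wide, n_patches = 6)
  expect_equal(c(gw$nx, gw$ny), c(3L, 2L))
  expect_error(make_patch_grid(pts, n_patches = 3), "\\[4, 16\\]")
  expect_error(make_patch_grid(pts, n_patches = 17), "\\[4, 16\\]")
})

test_that("extremal selection takes one max-z and one min-z particle per patch", {
  # two particles per patch at z = 0 and z = 100
  centers <- expand.grid(x = c(25, 75), y = c(25, 75))
  pts <- tibble::tibble(x = rep(centers$x, 2), y = rep(centers$y, 2),
                        z = rep(c(0, 100), each = 4))
  g <- make_patch_grid(pts, n_patches = 4)
  ext <- select_extremal(pts, g)
  expect_equal(nrow(ext$top), 4)
  expect_true(all(ext$top$z == 100))
  expect_true(all(ext$bottom$z == 0))
  # single occupancy: same particle lands in both sets
  one <- pts[1:4, ]
  ext1 <- select_extremal(one, make_patch_grid(one, n_patches = 4))
  expect_equal(ext1$top$row, ext1$bottom$row)
  # z-tie within a patch resolved to the lowest input row index
  tie <- tibble::tibble(x = c(10, 12, 60, 60, 10, 60), y = c(10, 10, 10, 10, 60, 60),
                        z = c(5, 5, 1, 1, 2, 3))
  gt <- make_patch_grid(tie, n_patches = 4)
  et <- select_extremal(tie, gt)
  expect_true(1 %in% et$top$row && !(2 %in% et$top$row))
  expect_true(3 %in% et$bottom$row && !(4 %in% et$bottom$row))
})

test_that("plane and quadric fits recover exact generating coefficients", {
  # 4 points exactly on z = 100
  flat <- tibble::tibble(x = c(0, 10, 0, 10), y = c(0, 0, 10, 10), z = 100)
  f <- fit_surface(flat, order = 1)
  expect_equal(unname(f$coeffs), c(100, 0, 0), tolerance = 1e-10)
  expect_equal(f$rms_residual, 0, tolerance = 1e-10)
  # 12 points on z = 50 + 0.05 x, zero noise, auto order stays planar
  set.seed(11)
  pts <- tibble::tibble(x = runif(12, 0, 500), y = runif(12, 0, 500))
  pts$z <- 50 + 0.05 * pts$x
  fa <- fit_surface(pts, order = "auto")
  expect_equal(fa$order, 1L)
  expect_equal(unname(fa$coeffs), c(50, 0.05, 0), tolerance = 1e-9)
  # order-2 exact recovery at <= 1e-6 rms
  cf2 <- c(80, 0.02, -0.01, 1e-4, -5e-5, 8e-5)
  q <- tibble::tibble(x = runif(20, 0, 400), y = runif(20, 0, 400))
  q$z <- poly_z(cf2, q$x, q$y)
  f2 <- fit_surface(q, order = 2)
  expect_equal(unname(f2$coeffs), cf2, tolerance = 1e-8)
  expect_lt(f2$rms_residual, 1e-6)
})

test_that("degenerate support geometry is rejected", {
  collinear <- tibble::tibble(x = c(0, 1, 2), y = c(0, 1, 2), z = c(5, 6, 7))
  expect_error(fit_surface(collinear, order = 1), "degenerate geometry")
  expect_error(fit_surface(collinear[1:2, ], order = 1), "insufficient")
  expect_error(fit_surface(uniform_slab(5), order = 2), "insufficient")
})

test_that("auto order upgrades only on >20% rms improvement with >= 9 supports", {
  set.seed(12)
  pts <- tibble::tibble(x = runif(30, 0, 300), y = runif(30, 0, 300))
  # strongly curved surface: auto must pick order 2
  pts$z <- poly_z(c(10, 0, 0, 5e-3, 0, 5e-3), pts$x, pts$y) + rnorm(30, 0, 0.1)
  expect_equal(fit_surface(pts, order = "auto")$order, 2L)
  # pure noise about a plane: stay at order 1
  pts$z <- 50 + rnorm(30, 0, 1)
  f <- fit_surface(pts, order = "auto")
  expect_equal(f$order, 1L)
  # with only 8 supports, never upgrade even if curved
  pts8 <- pts[1:8, ]
  pts8$z <- poly_z(c(10, 0, 0, 5e-3, 0, 5e-3), pts8$x, pts8$y)
  expect_equal(fit_surface(pts8, order = "auto")$order, 1L)
})

test_that("plane-coefficient error shrinks as the support count grows", {
  err_at <- function(n) {
    mean(replicate(50, {
      pts <- tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 500))
      pts$z <- 20 + 0.03 * pts$x - 0.01 * pts$y + rnorm(n, 0, 2)
      sqrt(sum((fit_surface(pts, order = 1)$coeffs - c(20, 0.03, -0.01))^2))
    }))
  }
  set.seed(21)
  errs <- vapply(c(6, 24, 96), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("closest distance to planes matches the analytic point-plane formula", {
  bot <- surface_from_coeffs(c(0, 0, 0), side = "bottom")
  expect_equal(closest_distance(c(0, 0, 5), bot), 5)
  expect_equal(closest_distance(c(0, 0, -5), bot), -5)
  # 45-degree tilt z = x: vertical gap d becomes d / sqrt(2)
  tilted <- surface_from_coeffs(c(0, 1, 0), side = "bottom")
  d <- 7.3
  expect_equal(closest_distance(c(0, 0, d), tilted), d / sqrt(2))
  # general plane, random points, machine precision
  cf <- c(30, 0.4, -0.7)
  s <- surface_from_coeffs(cf, side = "top")
  set.seed(31)
  pts <- tibble::tibble(x = runif(50, -100, 100), y = runif(50, -100, 100),
                        z = runif(50, -100, 100))
  expected <- (poly_z(cf, pts$x, pts$y) - pts$z) / sqrt(1 + cf[2]^2 + cf[3]^2)
  expect_equal(closest_distance(pts, s), expected, tolerance = 1e-12)
  # vertical mode reports the plain z-gap
  expect_equal(closest_distance(c(0, 0, d), tilted, mode = "vertical"), d)
  expect_error(closest_distance(c(0, NA, 1), bot), "finite")
})

test_that("quadric closest distance agrees with a dense grid-search oracle", {
  set.seed(41)
  for (i in 1:10) {
    cf <- c(runif(1, 20, 120), runif(2, -0.05, 0.05), runif(3, -1e-3, 1e-3))
    s <- surface_from_coeffs(cf, side = "bottom")
    p <- c(runif(1, 0, 500), runif(1, 0, 500), runif(1, -50, 200))
    got <- abs(closest_distance(p, s))
    expect_equal(got, grid_search_distance(p, cf), tolerance = 0.1)
  }
})

test_that("build_film recovers slab thickness and flags degenerate films", {
  # flat slab z in [0, 100], particles on both faces
  set.seed(51)
  n <- 200
  faces <- tibble::tibble(x = runif(2 * n, 0, 1000), y = runif(2 * n, 0, 1000),
                          z = rep(c(0, 100), each = n))
  film <- build_film(faces)
  expect_equal(film$mean_thickness_nm, 100, tolerance = 1)
  # tilted slab between z = 0.02 x and z = 0.02 x + 80: thickness exactly 80
  tilt <- faces
  tilt$z <- tilt$z * 0.8 + 0.02 * tilt$x
  film_t <- build_film(tilt)
  expect_equal(film_t$mean_thickness_nm, 80, tolerance = 1)
  # single layer -> zero-thickness error
  flat <- tibble::tibble(x = runif(50, 0, 100), y = runif(50, 0, 100), z = 42)
  expect_error(build_film(flat), "zero-thickness|inconsistent")
  expect_error(build_film(uniform_slab(5)), "insufficient")
  # crossing surfaces -> inconsistent-film error
  expect_error(film_from_coeffs(c(0, 0, 0), c(50, 0, 0),
                                xlim = c(0, 100), ylim = c(0, 100)),
               "inconsistent film")
})

test_that("bulk points have non-negative signed distance to both film surfaces", {
  set.seed(61)
  film <- film_from_coeffs(c(90, 0.01, -0.02, 2e-5, 0, -1e-5), c(5, 0.005, 0),
                           xlim = c(0, 800), ylim = c(0, 800))
  pts <- generate_film_particles(
    film_spec(area_x_nm = 800, area_y_nm = 800, applied_uM = 3,
              top_coeffs = c(90, 0.01, -0.02, 2e-5, 0, -1e-5),
              bottom_coeffs = c(5, 0.005, 0)),
    seed = 62)
  expect_gte(min(closest_distance(pts, film$top)), 0)
  expect_gte(min(closest_distance(pts, film$bottom)), 0)
})

test_that("tidy/glance expose film coefficients and summary", {
  set.seed(71)
  pts <- uniform_slab(300, thickness = 120)
  film <- build_film(pts)
  td <- tidy(film)
  expect_true(all(c("term", "estimate", "side") %in% names(td)))
  expect_setequal(unique(td$side), c("top", "bottom"))
  gl <- glance(film)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$mean_thickness_nm, 100)
})
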