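# shared fixture builders (all in-code; no stored data)

flat_film <- function(thickness = 100, xlim = c(0, 1000), ylim = c(0, 1000)) {
  film_from_coeffs(c(thickness, 0, 0), c(0, 0, 0), xlim = xlim, ylim = ylim)
}

# n particles uniform in a flat slab of the given thickness
uniform_slab <- function(n, thickness = 100, side = 1000, seed = 1) {
  set.seed(seed)
  tibble::tibble(x = runif(n, 0, side), y = runif(n, 0, side),
                 z = runif(n, 0, thickness))
}

# evaluate a polynomial surface z = c0 + cx x + cy y (+ quadratics)
poly_z <- function(coeffs, x, y) {
  z <- coeffs[1] + coeffs[2] * x + coeffs[3] * y
  if (length(coeffs) == 6) {
    z <- z + coeffs[4] * x^2 + coeffs[5] * x * y + coeffs[6] * y^2
  }
  z
}

# brute-force closest distance to z = f(x, y): staged dense grid search,
# coarse-to-fine around the running optimum
grid_search_distance <- function(p, coeffs) {
  best <- c(p[1], p[2])
  for (width in c(300, 4, 0.06)) {
    us <- seq(best[1] - width, best[1] + width, length.out = 301)
    vs <- seq(best[2] - width, best[2] + width, length.out = 301)
    g <- expand.grid(u = us, v = vs)
    d2 <- (g$u - p[1])^2 + (g$v - p[2])^2 + (poly_z(coeffs, g$u, g$v) - p[3])^2
    k <- which.min(d2)
    best <- c(g$u[k], g$v[k])
  }
  sqrt(min(d2))
}

expect_tsv_roundtrip <- function(tab, digits = 6) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(tab, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 10^-digits)
}
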