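#' Film volume over the analysis area
#'
#' Midpoint quadrature of `top(x, y) - bottom(x, y)` on a 50 x 50 grid over
#' the chosen x/y area, with negative gaps (locally crossing fits) clamped
#' to zero.
#'
#' @param film A `thin_film`.
#' @param area_mode `"particle-bounds"` (the bounding rectangle of the
#'   particles the film was fitted to; default) or `"tomogram-extent"`
#'   (requires `field_x_nm`/`field_y_nm` via `meta`).
#' @param meta An [acquisition_meta()] supplying tomogram extents for
#'   `"tomogram-extent"` mode.
#' @param eval_n Quadrature resolution per axis (default 50).
#' @return Volume in nm^3.
#' @export
film_volume <- function(film, area_mode = c("particle-bounds", "tomogram-extent"),
                        meta = NULL, eval_n = 50) {
  area_mode <- match.arg(area_mode)
  if (!inherits(film, "thin_film")) abort("`film` must be a thin_film.")
  if (area_mode == "particle-bounds") {
    xlim <- film$bounds$xlim
    ylim <- film$bounds$ylim
  } else {
    if (is.null(meta) || is.null(meta$field_x_nm) || is.null(meta$field_y_nm)) {
      abort("config error: tomogram-extent mode needs field_x_nm and field_y_nm in `meta`.")
    }
    xlim <- c(0, meta$field_x_nm)
    ylim <- c(0, meta$field_y_nm)
  }
  # midpoint rule: exact for polynomial thickness up to the cell scale
  hx <- diff(xlim) / eval_n
  hy <- diff(ylim) / eval_n
  xs <- xlim[1] + (seq_len(eval_n) - 0.5) * hx
  ys <- ylim[1] + (seq_len(eval_n) - 0.5) * hy
  g <- expand.grid(x = xs, y = ys)
  thick <- pmax(0, surface_eval(film$top, g$x, g$y) -
                  surface_eval(film$bottom, g$x, g$y))
  sum(thick) * hx * hy
}

#' Estimate the in-film molar concentration and its fold-change
#'
#' Converts a particle count in a film volume to micromolar using
#' 1 uM = 6.02214076e-7 particles per nm^3 (Avogadro's number at 1e-6 mol/L),
#' counting whole complexes as in the applied concentration.
#'
#' @param count Number of particles in the volume (>= 0).
#' @param volume_nm3 Film volume in nm^3 (> 0), e.g. from [film_volume()].
#' @param applied_uM Applied solution concentration in uM (> 0).
#' @return One-row tibble: `volume_nm3`, `count`, `conc_uM`, `applied_uM`,
#'   `fold_change` (= conc_uM / applied_uM).
#' @examples
#' estimate_concentration(100, 1e8, applied_uM = 0.8)
#' @export
estimate_concentration <- function(count, volume_nm3, applied_uM) {
  if (!is.numeric(volume_nm3) || length(volume_nm3) != 1 || volume_nm3 <= 0) {
    abort("`volume_nm3` must be a single positive volume.")
  }
  if (!is.numeric(count) || length(count) != 1 || count < 0) {
    abort("`count` must be a single non-negative number.")
  }
  if (!is.numeric(applied_uM) || length(applied_uM) != 1 || applied_uM <= 0) {
    abort("`applied_uM` must be a single positive concentration.")
  }
  conc <- (count / volume_nm3) / UM_PER_NM3
  tibble(volume_nm3 = volume_nm3, count = count, conc_uM = conc,
         applied_uM = applied_uM, fold_change = conc / applied_uM)
}
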