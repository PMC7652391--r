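deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# wrap into [-180, 180)
wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Canonicalize ZYZ Euler angles
#'
#' Brings tilt into \[0, 180\] degrees and rot/psi into \[-180, 180) without
#' changing the rotation they encode. A tilt in (180, 360) is folded as
#' (rot, tilt) -> (rot + 180, 360 - tilt), which leaves the view direction
#' unchanged.
#'
#' @param rot,tilt,psi Euler angles in degrees (ZYZ convention).
#' @return A tibble with columns `rot`, `tilt`, `psi` in canonical ranges.
#' @export
canonicalize_euler <- function(rot, tilt, psi = 0) {
  stopifnot(length(rot) == length(tilt))
  psi <- rep_len(psi, length(rot))
  tilt <- tilt %% 360
  flip <- tilt > 180
  rot[flip] <- rot[flip] + 180
  psi[flip] <- psi[flip] + 180
  tilt[flip] <- 360 - tilt[flip]
  tibble(rot = wrap180(rot), tilt = tilt, psi = wrap180(psi))
}

check_xyz <- function(particles, arg = "particles") {
  if (!is.data.frame(particles)) {
    abort(sprintf("`%s` must be a data frame with columns x, y, z.", arg))
  }
  missing <- setdiff(c("x", "y", "z"), names(particles))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing column(s): %s.", arg,
                  paste(missing, collapse = ", ")))
  }
  if (!all(vapply(particles[c("x", "y", "z")], is.numeric, logical(1))) ||
      !all(is.finite(particles$x) & is.finite(particles$y) &
           is.finite(particles$z))) {
    abort(sprintf("`%s` coordinates must be finite numbers.", arg))
  }
  invisible(particles)
}
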