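#' Acquisition metadata
#'
#' Bundles the pixel size, binning factor and (optionally) the tomogram x/y
#' extent so coordinate files recorded in pixels can be converted to
#' nanometers. The effective scale is `pixel_size_nm * binning` nm per
#' stored pixel unit.
#'
#' @param pixel_size_nm Physical pixel size of the unbinned data, nm/px.
#' @param binning Positive integer binning factor applied before picking.
#' @param field_x_nm,field_y_nm Optional tomogram extent in nm, used by
#'   [film_volume()] in `"tomogram-extent"` mode.
#' @param label Free-text identifier carried into reports.
#' @return An object of class `acquisition_meta`.
#' @examples
#' acquisition_meta(pixel_size_nm = 0.5, binning = 4)
#' @export
acquisition_meta <- function(pixel_size_nm = 1, binning = 1,
                             field_x_nm = NULL, field_y_nm = NULL,
                             label = "") {
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    abort("`pixel_size_nm` must be a single positive number.")
  }
  if (!is.numeric(binning) || length(binning) != 1 || binning < 1 ||
      binning != round(binning)) {
    abort("`binning` must be a positive integer.")
  }
  for (f in list(field_x_nm = field_x_nm, field_y_nm = field_y_nm)) {
    if (!is.null(f) && (!is.numeric(f) || f <= 0)) {
      abort("tomogram extents must be positive when given.")
    }
  }
  structure(
    list(pixel_size_nm = pixel_size_nm, binning = as.integer(binning),
         field_x_nm = field_x_nm, field_y_nm = field_y_nm,
         label = as.character(label)),
    class = "acquisition_meta"
  )
}

#' @export
print.acquisition_meta <- function(x, ...) {
  cat(sprintf("<acquisition_meta> %s: %.4g nm/px, binning %d (%.4g nm/unit)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$pixel_size_nm, x$binning, x$pixel_size_nm * x$binning))
  invisible(x)
}

# nm per stored coordinate unit
meta_scale <- function(meta) meta$pixel_size_nm * meta$binning

#' Read particle coordinates (and Euler angles)
#'
#' Reads a particle table from whitespace/comma-delimited text
#' (columns `x y z [rot tilt psi]`, `#` comments allowed) or from a STAR
#' file (relion coordinate and Euler-angle tags, plain or `loop_` blocks).
#' Coordinates stored in pixels are converted to nm using
#' `pixel_size_nm * binning` from `meta`; row order is preserved.
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"` (by extension), `"xyz"` or `"star"`.
#' @param meta An [acquisition_meta()]; defaults to the identity scale.
#' @param units `"px"` if the file stores pixel coordinates (converted to nm
#'   on read), `"nm"` if it already stores nm.
#' @return A tibble with columns `x`, `y`, `z` in nm and, when present in the
#'   file, canonicalized `rot`, `tilt`, `psi` in degrees. The `meta` object
#'   is attached as attribute `"meta"`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("# toy picks", "0 0 0", "1 1 1", "2 2 2"), f)
#' read_particles(f, meta = acquisition_meta(0.5, 4), units = "px")
#' @export
read_particles <- function(path, format = c("auto", "xyz", "star"),
                           meta = acquisition_meta(), units = c("nm", "px")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "xyz"
  }
  df <- if (format == "star") parse_star(path) else parse_xyz(path)
  if (nrow(df) == 0) {
    abort(sprintf("parse error: no particle rows found in %s", path))
  }
  scale <- if (units == "px") meta_scale(meta) else 1
  df$x <- df$x * scale
  df$y <- df$y * scale
  df$z <- df$z * scale
  if (all(c("rot", "tilt", "psi") %in% names(df))) {
    ang <- canonicalize_euler(df$rot, df$tilt, df$psi)
    df$rot <- ang$rot
    df$tilt <- ang$tilt
    df$psi <- ang$psi
  }
  attr(df, "meta") <- meta
  df
}

parse_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort(sprintf("parse error: %s contains no data lines", path))
  }
  toks <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  ncol <- vapply(toks, length, integer(1))
  if (any(ncol < 3)) {
    abort(sprintf("parse error at line %d of %s: expected >= 3 columns, got %d",
                  keep[which(ncol < 3)[1]], path, min(ncol)))
  }
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]]))
    if (anyNA(v)) {
      abort(sprintf("parse error at line %d of %s: non-numeric value '%s'",
                    keep[i], path, toks[[i]][which(is.na(v))[1]]))
    }
    v
  })
  has_angles <- all(ncol >= 6)
  out <- tibble(
    x = vapply(vals, `[`, numeric(1), 1),
    y = vapply(vals, `[`, numeric(1), 2),
    z = vapply(vals, `[`, numeric(1), 3)
  )
  if (has_angles) {
    out$rot <- vapply(vals, `[`, numeric(1), 4)
    out$tilt <- vapply(vals, `[`, numeric(1), 5)
    out$psi <- vapply(vals, `[`, numeric(1), 6)
  }
  out
}

STAR_TAGS <- c(
  x = "_rlnCoordinateX", y = "_rlnCoordinateY", z = "_rlnCoordinateZ",
  rot = "_rlnAngleRot", tilt = "_rlnAngleTilt", psi = "_rlnAnglePsi"
)

# Minimal STAR reader: first block containing the coordinate tags wins;
# unknown tags are ignored. Handles both loop_ and plain key-value blocks.
parse_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  n <- length(lines)
  i <- 1
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1
      tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, sub("\\s+#?[0-9]*$", "", strsplit(lines[j], "[[:space:]]+")[[1]][1]))
        j <- j + 1
      }
      rows <- list()
      while (j <= n && nzchar(lines[j]) && !startsWith(lines[j], "data_") &&
             lines[j] != "loop_" && !startsWith(lines[j], "_")) {
        rows[[length(rows) + 1]] <- strsplit(lines[j], "[[:space:]]+")[[1]]
        j <- j + 1
      }
      tab <- star_block_to_tibble(tags, rows, path)
      if (!is.null(tab)) return(tab)
      i <- j
    } else if (startsWith(lines[i], "_")) {
      # plain block: one value per tag line
      tags <- character(0)
      vals <- character(0)
      j <- i
      while (j <= n && startsWith(lines[j], "_")) {
        kv <- strsplit(lines[j], "[[:space:]]+")[[1]]
        if (length(kv) >= 2) {
          tags <- c(tags, kv[1])
          vals <- c(vals, kv[2])
        }
        j <- j + 1
      }
      tab <- star_block_to_tibble(tags, list(vals), path)
      if (!is.null(tab)) return(tab)
      i <- j
    } else {
      i <- i + 1
    }
  }
  abort(sprintf(
    "format error: no STAR block with coordinate columns (%s) found in %s",
    paste(STAR_TAGS[c("x", "y", "z")], collapse = ", "), path))
}

star_block_to_tibble <- function(tags, rows, path) {
  idx <- match(STAR_TAGS[c("x", "y", "z")], tags)
  if (anyNA(idx)) return(NULL)
  if (length(rows) == 0) {
    abort(sprintf("parse error: STAR loop in %s declares columns but has no rows",
                  path))
  }
  aidx <- match(STAR_TAGS[c("rot", "tilt", "psi")], tags)
  cols <- c("x", "y", "z", if (!anyNA(aidx)) c("rot", "tilt", "psi"))
  take <- c(idx, if (!anyNA(aidx)) aidx)
  out <- lapply(seq_along(take), function(k) {
    v <- vapply(rows, function(r) {
      if (length(r) < take[k]) NA_character_ else r[take[k]]
    }, character(1))
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) {
      abort(sprintf("parse error in %s: non-numeric value '%s' in row %d of column %s",
                    path, v[which(is.na(num))[1]], which(is.na(num))[1],
                    STAR_TAGS[cols[k]]))
    }
    num
  })
  names(out) <- cols
  as_tibble(out)
}

#' Write a per-tomogram summary report
#'
#' One row per tomogram: particle count, mean film thickness, bound fraction
#' at both the 10 nm and 20 nm thresholds, top/bottom counts at the applied
#' threshold, in-film concentration and fold-change. Columns are written in a
#' fixed order so reports are byte-reproducible.
#'
#' @param results A list; each element is a list with components
#'   `label`, `partition` (an `awi_partition`, threshold as applied),
#'   `partition_10`, `partition_20` (the two fixed-threshold partitions) and
#'   `concentration` (one-row tibble from [estimate_concentration()]).
#'   `partition_10`/`partition_20` may be omitted, in which case they are
#'   recomputed from `partition`'s stored distances.
#' @param path Output path; tab-separated text.
#' @return The report tibble, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.list(results) || length(results) == 0) {
    abort("`results` must be a non-empty list of per-tomogram result sets.")
  }
  rows <- purrr::map(results, function(r) {
    p <- r$partition
    if (is.null(p) || !inherits(p, "awi_partition")) {
      abort("each result needs a `partition` of class awi_partition.")
    }
    p10 <- r$partition_10 %||% repartition(p, 10)
    p20 <- r$partition_20 %||% repartition(p, 20)
    conc <- r$concentration
    tibble(
      label = r$label %||% "",
      n_particles = nrow(p$particles),
      mean_thickness_nm = p$mean_thickness_nm,
      threshold_nm = p$threshold_nm,
      bound_fraction = p$bound_fraction,
      bound_fraction_10nm = p10$bound_fraction,
      bound_fraction_20nm = p20$bound_fraction,
      n_top = p$n_top,
      n_middle = p$n_middle,
      n_bottom = p$n_bottom,
      asymmetry_index = p$asymmetry_index,
      conc_uM = if (is.null(conc)) NA_real_ else conc$conc_uM,
      applied_uM = if (is.null(conc)) NA_real_ else conc$applied_uM,
      fold_change = if (is.null(conc)) NA_real_ else conc$fold_change
    )
  })
  report <- dplyr::bind_rows(rows)
  tryCatch(
    readr::write_tsv(report, path),
    error = function(e) abort(sprintf("cannot write report to %s: %s",
                                      path, conditionMessage(e)))
  )
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration file
#'
#' YAML with optional sections `input`, `surfaces`, `partition`,
#' `orientation`, `simulate`; unknown sections are kept as-is.
#'
#' @param path Path to a YAML file.
#' @return A named list of sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("config must be a YAML mapping of sections.")
  cfg
}
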