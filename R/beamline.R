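# Geometry of the dual-foil system and the segmented secondary foil.

#' Beamline geometry
#'
#' Axial layout of the dual-foil system. The origin `z = 0` is the top of
#' the primary foil; the top of the secondary foil sits at `z1` and the
#' calculation plane at `z2 = SAD + calc_depth`, with the isocenter at
#' `z = SAD`. The source-to-axis distance is measured from the primary
#' foil, so `d_primary_secondary + d_secondary_iso` must equal `SAD`.
#'
#' @param d_window_primary Vacuum exit window to primary foil distance, cm.
#' @param d_primary_secondary Primary to secondary foil distance, cm.
#' @param d_secondary_iso Secondary foil to isocenter distance, cm.
#' @param SAD Source-to-axis distance, cm (default 100). If `NULL` it is
#'   derived from the two downstream distances.
#' @param calc_depth Isocenter to calculation plane distance ("calculation
#'   depth") `d`, cm; profiles computed in air at `z2` stand in for
#'   shallow-depth dose in water, so depths above 2 cm trigger a warning.
#' @return Object of class `beamline_geometry` with derived planes
#'   `z_window`, `z1`, `z_iso`, `z2`.
#' @export
#' @examples
#' beamline_geometry(3, 15, 85, calc_depth = 2)
beamline_geometry <- function(d_window_primary = 3, d_primary_secondary = 15,
                              d_secondary_iso = 85, SAD = NULL,
                              calc_depth = 2) {
  stopifnot(d_window_primary > 0, d_primary_secondary > 0,
            d_secondary_iso > 0, calc_depth > 0)
  derived <- d_primary_secondary + d_secondary_iso
  if (is.null(SAD)) SAD <- derived
  if (abs(SAD - derived) > 1e-9)
    stop(sprintf("inconsistent geometry: d_primary_secondary + d_secondary_iso = %.6g cm but SAD = %.6g cm",
                 derived, SAD))
  if (calc_depth > 2)
    warning("calculation depth ", calc_depth,
            " cm exceeds 2 cm; the in-air profile is only a valid proxy ",
            "for dose in water at shallow depths")
  structure(list(d_window_primary = d_window_primary,
                 d_primary_secondary = d_primary_secondary,
                 d_secondary_iso = d_secondary_iso,
                 SAD = SAD, calc_depth = calc_depth,
                 z_window = -d_window_primary,
                 z1 = d_primary_secondary,
                 z_iso = SAD,
                 z2 = SAD + calc_depth),
            class = "beamline_geometry")
}

#' @export
print.beamline_geometry <- function(x, ...) {
  cat(sprintf(paste0("<beamline geometry> window %.4g | primary 0 | ",
                     "secondary %.4g | iso %.4g | calc plane %.4g cm\n"),
              x$z_window, x$z1, x$z_iso, x$z2))
  invisible(x)
}

#' Gaussian secondary-foil specification
#'
#' @param material Material name or `foil_material` (typically aluminum).
#' @param t0 Central-axis thickness, cm.
#' @param sigma Sigma of the Gaussian cross-section, cm.
#' @param n_segments Number of equally spaced radial segments used to
#'   approximate the Gaussian (how such foils are machined).
#' @param r_max Maximum foil radius, cm (default 3.65).
#' @return Object of class `gaussian_foil_spec`.
#' @export
gaussian_foil_spec <- function(material, t0, sigma, n_segments, r_max = 3.65) {
  mat <- get_material(material)
  stopifnot(t0 > 0, sigma > 0, r_max > 0)
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 1L)
    stop("n_segments must be a positive integer")
  structure(list(material = mat, t0 = t0, sigma = sigma,
                 n_segments = n_segments, r_max = r_max),
            class = "gaussian_foil_spec")
}

#' Gaussian foil thickness profile
#'
#' @param r Radius, cm (vectorized, >= 0).
#' @param spec A `gaussian_foil_spec`.
#' @return Thickness `t0 exp(-r^2 / (2 sigma^2))`, cm.
#' @export
gaussian_thickness <- function(r, spec) {
  stopifnot(inherits(spec, "gaussian_foil_spec"), all(r >= 0))
  spec$t0 * exp(-r^2 / (2 * spec$sigma^2))
}

#' Construct a segmented foil
#'
#' @param boundaries Strictly increasing outer radii of the annuli, cm.
#' @param thicknesses Per-annulus thicknesses, cm (same length).
#' @param material Material name or `foil_material`.
#' @return Object of class `segmented_foil`. Thickness beyond the last
#'   boundary is zero; a boundary radius belongs to the inner annulus.
#' @export
segmented_foil <- function(boundaries, thicknesses, material) {
  mat <- get_material(material)
  stopifnot(length(boundaries) == length(thicknesses),
            length(boundaries) >= 1)
  if (any(diff(boundaries) <= 0) || boundaries[1] <= 0)
    stop("foil boundaries must be positive and strictly increasing")
  if (any(thicknesses < 0)) stop("foil thicknesses must be >= 0")
  structure(list(boundaries = as.numeric(boundaries),
                 thicknesses = as.numeric(thicknesses), material = mat),
            class = "segmented_foil")
}

#' @export
print.segmented_foil <- function(x, ...) {
  cat(sprintf("<segmented foil> %s, %d segments, r_max = %.4g cm, t(0) = %.4g cm\n",
              x$material$name, length(x$boundaries),
              max(x$boundaries), x$thicknesses[1]))
  invisible(x)
}

#' Segment a Gaussian foil
#'
#' Approximates the Gaussian cross-section by `n_segments` equally spaced
#' annuli on `[0, r_max]`. The descending edge of each step crosses the
#' true Gaussian at its midpoint: at every internal boundary `r_k`,
#' `(t_k + t_[k+1]) / 2 = t0 exp(-r_k^2/(2 sigma^2))`. The midpoint rule
#' fixes only differences, so the stack is anchored by setting the
#' innermost thickness to the area-weighted mean of the true Gaussian
#' over the central disc; thicknesses are clamped at zero.
#'
#' @param spec A `gaussian_foil_spec`.
#' @return A `segmented_foil`.
#' @export
#' @examples
#' spec <- gaussian_foil_spec("aluminum", t0 = 0.6, sigma = 1.44,
#'                            n_segments = 25)
#' segment_gaussian_foil(spec)
segment_gaussian_foil <- function(spec) {
  stopifnot(inherits(spec, "gaussian_foil_spec"))
  n <- spec$n_segments
  b <- seq_len(n) * spec$r_max / n
  if (n == 1L)
    return(segmented_foil(b, spec$t0, spec$material))
  # area-weighted mean of t0 exp(-r^2/(2 s^2)) over the disc r < b1
  s2 <- spec$sigma^2
  t1 <- spec$t0 * 2 * s2 / b[1]^2 * (1 - exp(-b[1]^2 / (2 * s2)))
  t <- numeric(n)
  t[1] <- t1
  for (k in seq_len(n - 1L))
    t[k + 1L] <- max(0, 2 * gaussian_thickness(b[k], spec) - t[k])
  segmented_foil(b, t, spec$material)
}

#' Piecewise-constant foil thickness lookup
#'
#' @param foil A `segmented_foil`.
#' @param r Radius, cm (vectorized, >= 0). A radius exactly on an
#'   internal boundary takes the inner annulus value; radii beyond the
#'   last boundary return 0.
#' @return Thickness, cm.
#' @export
local_thickness <- function(foil, r) {
  stopifnot(inherits(foil, "segmented_foil"), all(r >= 0))
  idx <- findInterval(r, foil$boundaries, left.open = TRUE) + 1L
  out <- numeric(length(r))
  inside <- idx <= length(foil$thicknesses)
  out[inside] <- foil$thicknesses[idx[inside]]
  out
}

# smallest positive segment thickness (floor for thin-slab Moliere B)
.min_positive_thickness <- function(foil) {
  tp <- foil$thicknesses[foil$thicknesses > 0]
  if (length(tp) == 0) stop("foil has no positive-thickness segment")
  min(tp)
}

#' Write a secondary-foil geometry file
#'
#' CSV with a `# material=<name>` comment line and header
#' `r_outer_cm,thickness_cm`; full double precision, lossless round-trip.
#'
#' @param foil A `segmented_foil`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_secondary_foil_file <- function(foil, path) {
  stopifnot(inherits(foil, "segmented_foil"))
  lines <- c(sprintf("# material=%s", foil$material$name),
             "r_outer_cm,thickness_cm",
             sprintf("%.17g,%.17g", foil$boundaries, foil$thicknesses))
  writeLines(lines, path)
  invisible(path)
}

#' Read a secondary-foil geometry file
#'
#' @param path File path (format of [write_secondary_foil_file()]).
#' @return A `segmented_foil`.
#' @export
load_secondary_foil_file <- function(path) {
  if (!file.exists(path)) stop("foil file not found: ", path)
  lines <- readLines(path)
  mat_line <- grep("^#\\s*material\\s*=", lines, value = TRUE)
  if (length(mat_line) == 0)
    stop("foil file lacks a '# material=<name>' line: ", path)
  mat_name <- trimws(sub("^#\\s*material\\s*=", "", mat_line[1]))
  mat <- get_material(mat_name)  # errors naming the registry if unknown
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  body <- lines[body_idx]
  if (length(body) < 2) stop("foil file has no data rows: ", path)
  header <- body[1]
  rows <- body[-1]
  rows_idx <- body_idx[-1]
  if (!grepl("r_outer_cm", header))
    stop("foil file missing 'r_outer_cm,thickness_cm' header: ", path)
  r <- numeric(length(rows)); t <- numeric(length(rows))
  for (i in seq_along(rows)) {
    parts <- strsplit(trimws(rows[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || anyNA(vals))
      stop(sprintf("foil file parse error at line %d: '%s'",
                   rows_idx[i], rows[i]))
    r[i] <- vals[1]; t[i] <- vals[2]
  }
  if (any(diff(r) <= 0))
    stop(sprintf("foil radii must be strictly increasing (line %d)",
                 rows_idx[which(diff(r) <= 0)[1] + 1L]))
  segmented_foil(r, t, mat)
}
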