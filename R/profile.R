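# Radial profile container and two-column profile file I/O.

#' Construct a radial profile
#'
#' @param r Radial positions, cm. Either a symmetric grid about 0 or a
#'   non-negative half-grid (mirroring is implied by axisymmetry).
#' @param v Values at `r` (finite).
#' @param normalization One of `"cax_1"` (1.0 on the central axis),
#'   `"cax_100"` (100% on the central axis), `"absolute_per_electron"`
#'   (planar fluence per incident electron, 1/cm^2) or
#'   `"percent_of_cax_dmax"` (percent of the central-axis dose maximum,
#'   used for X-ray dose profiles).
#' @return Object of class `foil_profile`.
#' @export
foil_profile <- function(r, v,
                         normalization = c("cax_1", "cax_100",
                                           "absolute_per_electron",
                                           "percent_of_cax_dmax")) {
  normalization <- match.arg(normalization)
  r <- as.numeric(r); v <- as.numeric(v)
  stopifnot(length(r) == length(v), length(r) >= 1)
  if (anyNA(r) || any(!is.finite(v)))
    stop("profile positions/values must be finite")
  if (is.unsorted(r, strictly = TRUE)) stop("profile positions must be strictly increasing")
  if (any(r < 0)) {
    # symmetric grid: must straddle zero
    if (max(r) <= 0) stop("a symmetric profile grid must extend to r > 0")
  }
  p <- structure(list(r = r, v = v, normalization = normalization),
                 class = "foil_profile")
  if (normalization %in% c("cax_1", "cax_100") && any(r == 0)) {
    target <- if (normalization == "cax_1") 1 else 100
    if (abs(v[r == 0] - target) > 1e-9)
      stop(sprintf("profile tagged '%s' must have v(0) = %g (got %.12g)",
                   normalization, target, v[r == 0]))
  }
  p
}

#' @export
print.foil_profile <- function(x, ...) {
  cat(sprintf("<profile> %d points, r in [%.4g, %.4g] cm, %s\n",
              length(x$r), min(x$r), max(x$r), x$normalization))
  invisible(x)
}

#' Linear interpolation of a profile
#'
#' Strictly interpolating: requesting a position outside the profile
#' support is an error (no extrapolation). Half-grid profiles are
#' mirrored about the axis first.
#'
#' @param profile A `foil_profile`.
#' @param r Positions, cm.
#' @return Interpolated values.
#' @export
profile_interp <- function(profile, r) {
  p <- mirror_profile(profile)
  if (any(r < min(p$r) - 1e-12 | r > max(p$r) + 1e-12))
    stop(sprintf("position %.4g cm outside profile support [%.4g, %.4g]",
                 r[which(r < min(p$r) | r > max(p$r))[1]], min(p$r), max(p$r)))
  stats::approx(p$r, p$v, xout = r, rule = 2)$y
}

#' Mirror a half-grid profile onto a symmetric grid
#'
#' @param profile A `foil_profile`. Profiles already containing negative
#'   radii are returned unchanged.
#' @return A `foil_profile` on a grid symmetric about 0.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "foil_profile"))
  if (any(profile$r < 0)) return(profile)
  r <- profile$r; v <- profile$v
  if (r[1] == 0) {
    r_full <- c(-rev(r[-1]), r); v_full <- c(rev(v[-1]), v)
  } else {
    r_full <- c(-rev(r), r); v_full <- c(rev(v), v)
  }
  foil_profile(r_full, v_full, profile$normalization)
}

#' Read a two-column profile file
#'
#' Whitespace- or comma-delimited `(position_cm, relative_dose)` rows;
#' lines starting with `#` are comments.
#'
#' @param path File path.
#' @param normalization Normalization tag to attach. The default
#'   (`"percent_of_cax_dmax"`) places no constraint on the central-axis
#'   value, which suits comparison/objective files on either scale.
#' @return A `foil_profile`.
#' @export
read_profile_file <- function(path,
                              normalization = "percent_of_cax_dmax") {
  if (!file.exists(path)) stop("profile file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) stop("profile file has no data rows: ", path)
  r <- numeric(length(keep)); v <- numeric(length(keep))
  for (i in seq_along(keep)) {
    parts <- strsplit(trimws(lines[keep[i]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != 2 || anyNA(vals))
      stop(sprintf("profile file parse error at line %d: '%s'",
                   keep[i], lines[keep[i]]))
    r[i] <- vals[1]; v[i] <- vals[2]
  }
  ord <- order(r)
  foil_profile(r[ord], v[ord], normalization)
}

#' Write a two-column profile file
#'
#' Values are written with 9 significant digits, so a read/write
#' round-trip is lossless at that precision.
#'
#' @param profile A `foil_profile`.
#' @param path Output path.
#' @param header Optional comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_profile_file <- function(profile, path, header = NULL) {
  stopifnot(inherits(profile, "foil_profile"))
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  lines <- c(lines, sprintf("%.9g %.9g", profile$r, profile$v))
  writeLines(lines, path)
  invisible(path)
}
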