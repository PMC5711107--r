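# Simulation configuration: defaults, validation and key=value file I/O.

#' Default simulation configuration
#'
#' Nested list mirroring the simulator's control panes. Calculation
#' defaults follow the simulator's standard settings: 30 cm profile
#' half-range, 100 integration points in radius and angle, 60 profile
#' points and a 3.65 cm maximum secondary-foil radius; flatness defaults
#' to a +/-3% criterion over +/-14.6 cm. Geometry distances are generic
#' placeholders and should be set to the accelerator being modeled.
#'
#' @param ... Named overrides applied on top of the defaults, e.g.
#'   `simulation_config(beam = list(energy = 20))`. Overrides are merged
#'   per section.
#' @return Configuration list of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(primary_foil = list(thickness = 0.011))
simulation_config <- function(...) {
  cfg <- list(
    beam = list(energy = 13.99, mode = "incident_mean", ep0_offset = 0),
    geometry = list(d_window_primary = 3, d_primary_secondary = 15,
                    d_secondary_iso = 85, SAD = 100, calc_depth = 2),
    window = list(material = "nickel", thickness = 0.0125),
    primary_foil = list(material = "tantalum", thickness = 0.008),
    secondary_foil = list(mode = "gaussian", material = "aluminum",
                          t0 = 0.6, sigma = 1.44, n_segments = 25,
                          r_max = 3.65, file = ""),
    calculation = list(half_range = 30, n_rho = 100, n_theta = 100,
                       n_profile = 60, kernel = "conditional",
                       t_secondary = "fluence_weighted"),
    xray = list(include = TRUE, a = -0.035, b = 15.77, c = 0.016),
    flatness = list(range = 14.6, criterion = 3)
  )
  overrides <- list(...)
  if (length(overrides) &&
      (is.null(names(overrides)) || any(!nzchar(names(overrides)))))
    stop("overrides must be named sections, e.g. beam = list(energy = 20)")
  for (sec in names(overrides)) {
    if (!sec %in% names(cfg))
      stop("unknown configuration section '", sec, "'; valid sections: ",
           paste(names(cfg), collapse = ", "))
    for (key in names(overrides[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop(sprintf("unknown key '%s' in section [%s]; valid keys: %s",
                     key, sec, paste(names(cfg[[sec]]), collapse = ", ")))
      cfg[[sec]][[key]] <- overrides[[sec]][[key]]
    }
  }
  class(cfg) <- "simulation_config"
  cfg
}

#' Validate a simulation configuration
#'
#' Checks value ranges and mode enumerations; errors list the offending
#' section/key.
#'
#' @param config A `simulation_config` (or plain nested list).
#' @return The validated configuration, invisibly classed.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  chk <- function(ok, what) if (!isTRUE(ok)) bad <<- c(bad, what)
  chk(is.numeric(config$beam$energy) && config$beam$energy > 0,
      "beam.energy > 0")
  chk(config$beam$mode %in% c("incident_mean", "surface_Ep0"),
      "beam.mode in {incident_mean, surface_Ep0}")
  g <- config$geometry
  chk(all(vapply(g[c("d_window_primary", "d_primary_secondary",
                     "d_secondary_iso", "calc_depth")], function(x)
    is.numeric(x) && x > 0, TRUE)), "geometry distances > 0")
  chk(config$window$thickness > 0, "window.thickness > 0")
  chk(config$primary_foil$thickness > 0, "primary_foil.thickness > 0")
  sf <- config$secondary_foil
  chk(sf$mode %in% c("gaussian", "file", "none"),
      "secondary_foil.mode in {gaussian, file, none}")
  if (identical(sf$mode, "gaussian"))
    chk(sf$t0 > 0 && sf$sigma > 0 && sf$n_segments >= 1 && sf$r_max > 0,
        "secondary_foil gaussian spec (t0, sigma, n_segments, r_max)")
  if (identical(sf$mode, "file"))
    chk(is.character(sf$file) && nzchar(sf$file), "secondary_foil.file set")
  cc <- config$calculation
  chk(cc$half_range > 0 && cc$n_rho >= 4 && cc$n_theta >= 4 &&
        cc$n_profile >= 2, "calculation grid sizes")
  chk(cc$kernel %in% c("conditional", "uncorrelated"),
      "calculation.kernel in {conditional, uncorrelated}")
  chk(cc$t_secondary %in% c("fluence_weighted", "cax"),
      "calculation.t_secondary in {fluence_weighted, cax}")
  chk(is.logical(config$xray$include) || config$xray$include %in% c(0, 1),
      "xray.include boolean")
  chk(config$flatness$range > 0 && config$flatness$criterion >= 0,
      "flatness settings")
  if (length(bad))
    stop("invalid configuration: ", paste(bad, collapse = "; "))
  config$xray$include <- as.logical(config$xray$include)
  class(config) <- "simulation_config"
  invisible(config)
}

.fmt_value <- function(x) {
  if (is.logical(x)) return(if (x) "true" else "false")
  if (is.numeric(x)) return(sprintf("%.17g", x))
  as.character(x)
}

.parse_value <- function(s) {
  s <- trimws(s)
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

#' Write a configuration file
#'
#' `[section]` / `key = value` structured text mirroring the simulator's
#' control panes; round-trips losslessly through [read_config()].
#'
#' @param config A `simulation_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- character(0)
  for (sec in names(config)) {
    lines <- c(lines, sprintf("[%s]", sec))
    for (key in names(config[[sec]]))
      lines <- c(lines, sprintf("%s = %s", key,
                                .fmt_value(config[[sec]][[key]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a configuration file
#'
#' @param path Path to a `[section]` / `key = value` file as written by
#'   [write_config()]. Unknown sections or keys are schema errors.
#' @return A validated `simulation_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  cfg <- simulation_config()
  sec <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(sub("[#;].*$", "", lines[i]))
    if (!nzchar(ln)) next
    if (grepl("^\\[.+\\]$", ln)) {
      sec <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!sec %in% names(cfg))
        stop(sprintf("config line %d: unknown section [%s]", i, sec))
      next
    }
    if (!grepl("=", ln) || is.null(sec))
      stop(sprintf("config line %d: expected 'key = value' inside a section: '%s'",
                   i, lines[i]))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg[[sec]]))
      stop(sprintf("config line %d: unknown key '%s' in section [%s]",
                   i, key, sec))
    cfg[[sec]][[key]] <- .parse_value(val)
  }
  validate_config(cfg)
}
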