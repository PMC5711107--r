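# End-to-end simulation, parameter sweeps and design checking.

#' Run a full dual-foil simulation
#'
#' Transports the beam through the configured beamline, computes the
#' off-axis electron relative dose profile, the X-ray contamination
#' component (when enabled and at least one scatterer is present), the
#' combined total relative dose profile and a flatness evaluation
#' against a flat objective.
#'
#' @param config A [simulation_config()].
#' @param check_convergence Logical; verify the polar quadrature by
#'   doubling the integration points (roughly doubles run time).
#' @return Object of class `foilsim_result` with elements `electron`,
#'   `xray`, `total` (profiles on one symmetric grid), `flatness`,
#'   `budget`, `summary` (energies, Ke, Rp, X, central-axis X-ray
#'   percentages) and `config`.
#' @export
#' @examples
#' \donttest{
#' res <- run_simulation(simulation_config())
#' print(res)
#' }
run_simulation <- function(config = simulation_config(),
                           check_convergence = FALSE) {
  setup <- .build_transport(config)
  config <- setup$config
  geom <- setup$geometry
  en <- setup$energies

  fluence <- electron_fluence_profile(config, setup = setup,
                                      check_convergence = check_convergence)
  electron <- electron_dose_profile(fluence, en$Ep0, geom$calc_depth)
  Rp <- practical_range(en$Ep0)

  budget <- NULL; xray <- NULL; pct_d <- 0; pct_Rp2 <- NA_real_; X <- NA_real_
  if (isTRUE(config$xray$include)) {
    cal <- xray_calibration(config$xray$a, config$xray$b, config$xray$c)
    budget <- build_xray_budget(config$window, config$primary_foil,
                                setup$foil, en, setup$fluence_z1,
                                config$calculation$t_secondary)
    xray <- offaxis_xray_percent_profile(budget, cal, geom, en$Ep0,
                                         attr(fluence, "cax_absolute"),
                                         electron$r)
    X <- attr(xray, "X")
    pct_Rp2 <- attr(xray, "cax_pct_Rp2")
    pct_d <- attr(xray, "cax_pct_at_d")
  }
  total <- total_dose_profile(electron, xray, pct_d)

  objective <- foil_profile(range(total$r), c(100, 100),
                            "percent_of_cax_dmax")
  flat <- flatness_report(total, objective, config$flatness$range,
                          config$flatness$criterion)

  structure(list(
    electron = electron, xray = xray, total = total, flatness = flat,
    budget = budget, config = config,
    summary = list(
      E_incident = en$E_incident, E0_mean = en$E0_mean, Ep0 = en$Ep0,
      Ed = attr(electron, "Ed"), Ke = attr(electron, "Ke"), Rp = Rp,
      cax_fluence_per_electron = attr(fluence, "cax_absolute"),
      X = X, cax_xray_pct_Rp2 = pct_Rp2, cax_xray_pct_at_d = pct_d,
      sigma_r = attr(fluence, "sigma_r"))),
    class = "foilsim_result")
}

#' @export
print.foilsim_result <- function(x, ...) {
  s <- x$summary
  cat("== dual scattering foil simulation ==\n")
  cat(sprintf("  incident mean energy  : %8.3f MeV\n", s$E_incident))
  cat(sprintf("  mean energy at surface: %8.3f MeV (Ep0 display %.3f MeV)\n",
              s$E0_mean, s$Ep0))
  cat(sprintf("  Ke(Ed = %.2f MeV)     : %8.4f MeV cm^2/g\n", s$Ed, s$Ke))
  cat(sprintf("  practical range Rp    : %8.3f cm\n", s$Rp))
  if (!is.na(s$X)) {
    cat(sprintf("  X statistic           : %8.3f MeV\n", s$X))
    cat(sprintf("  X-ray %%D at Rp+2 cm   : %8.3f %%\n", s$cax_xray_pct_Rp2))
    cat(sprintf("  X-ray %%D at depth d   : %8.3f %%\n", s$cax_xray_pct_at_d))
  }
  print(x$flatness)
  invisible(x)
}

#' Plot a simulation result
#'
#' Total, electron and X-ray relative dose profiles with the flatness
#' range and criterion marked.
#'
#' @param x A `foilsim_result`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.foilsim_result <- function(x, ...) {
  graphics::plot(x$total$r, x$total$v, type = "l", lwd = 2,
                 xlab = "off-axis distance (cm)",
                 ylab = "relative dose (% of CAX)", ylim = c(0, 115), ...)
  graphics::lines(x$electron$r, 100 * x$electron$v, lty = 2)
  if (!is.null(x$xray))
    graphics::lines(x$xray$r, 10 * x$xray$v, lty = 3)
  fl <- x$flatness
  graphics::abline(v = c(-1, 1) * fl$eval_range, col = "red")
  graphics::abline(h = 100 + c(-1, 1) * fl$criterion, col = "grey50",
                   lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 2, 3),
                   legend = c("total", "electron", "X-ray x 10"))
  invisible(x)
}

#' Write simulation outputs to files
#'
#' Writes `electron_profile.txt`, `xray_profile.txt` (when computed),
#' `total_profile.txt` and `summary.txt` into `output_dir`. Output is
#' deterministic at fixed precision: identical configurations produce
#' byte-identical files.
#'
#' @param config A [simulation_config()] (or path to a config file).
#' @param output_dir Output directory (created if needed).
#' @param ... Passed to [run_simulation()].
#' @return The `foilsim_result`, invisibly.
#' @export
simulate_to_files <- function(config, output_dir, ...) {
  if (is.character(config)) config <- read_config(config)
  res <- run_simulation(config, ...)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_file(res$electron, file.path(output_dir,
                                             "electron_profile.txt"),
                     header = "electron relative dose (cax = 1)")
  if (!is.null(res$xray))
    write_profile_file(res$xray, file.path(output_dir, "xray_profile.txt"),
                       header = "X-ray dose (% of CAX dose maximum)")
  write_profile_file(res$total, file.path(output_dir, "total_profile.txt"),
                     header = "total relative dose (cax = 100)")
  s <- res$summary
  fl <- res$flatness
  summary_lines <- c(
    sprintf("E_incident_MeV = %.6f", s$E_incident),
    sprintf("E0_mean_MeV = %.6f", s$E0_mean),
    sprintf("Ep0_MeV = %.6f", s$Ep0),
    sprintf("Ke_MeV_cm2_g = %.6f", s$Ke),
    sprintf("Rp_cm = %.6f", s$Rp),
    sprintf("X_MeV = %.6f", if (is.na(s$X)) 0 else s$X),
    sprintf("cax_xray_pct_Rp2 = %.6f",
            if (is.na(s$cax_xray_pct_Rp2)) 0 else s$cax_xray_pct_Rp2),
    sprintf("cax_xray_pct_at_d = %.6f", s$cax_xray_pct_at_d),
    sprintf("flatness_over_pct = %.6f", fl$max_over),
    sprintf("flatness_under_pct = %.6f", fl$max_under))
  writeLines(summary_lines, file.path(output_dir, "summary.txt"))
  invisible(res)
}

.sweep_params <- c("primary.thickness", "secondary.t0", "secondary.sigma",
                   "beam.energy")

#' Sweep a design parameter
#'
#' Re-runs the simulation across a set of values of one design parameter
#' (the slider-bar workflow) and tabulates flatness and central-axis
#' X-ray dose.
#'
#' @param config Base [simulation_config()].
#' @param parameter One of `"primary.thickness"`, `"secondary.t0"`,
#'   `"secondary.sigma"`, `"beam.energy"`.
#' @param values Numeric vector of at least two parameter values.
#' @return Data frame sorted by `value` with columns `value`,
#'   `flatness_over`, `flatness_under`, `cax_xray_pct` (at Rp + 2),
#'   `horn_max` (maximum of the total profile over the off-axis
#'   shoulder/horn region, 5 cm out to the flatness range, % of CAX).
#' @export
sweep_parameter <- function(config, parameter, values) {
  if (!parameter %in% .sweep_params)
    stop("unknown sweep parameter '", parameter, "'; valid parameters: ",
         paste(.sweep_params, collapse = ", "))
  if (length(values) < 2) stop("a sweep needs at least 2 values")
  values <- sort(values)
  rows <- lapply(values, function(v) {
    cfg <- config
    switch(parameter,
           "primary.thickness" = cfg$primary_foil$thickness <- v,
           "secondary.t0" = cfg$secondary_foil$t0 <- v,
           "secondary.sigma" = cfg$secondary_foil$sigma <- v,
           "beam.energy" = cfg$beam$energy <- v)
    res <- run_simulation(cfg)
    horn <- abs(res$total$r) >= 5 &
      abs(res$total$r) <= cfg$flatness$range
    data.frame(value = v, flatness_over = res$flatness$max_over,
               flatness_under = res$flatness$max_under,
               cax_xray_pct = res$summary$cax_xray_pct_Rp2,
               horn_max = max(res$total$v[horn]))
  })
  do.call(rbind, rows)
}

#' Check a design against an objective profile
#'
#' Evaluates the flatness of the simulated total dose profile against an
#' objective profile read from file, and (when a reference profile from
#' measurement or Monte Carlo is supplied) writes a refined objective
#' per [refine_objective()] on the flatness-range grid.
#'
#' Objective/reference files with values on a unit scale (maximum at or
#' near 1) are rescaled by 100 to the total-dose percent scale.
#'
#' @param config A [simulation_config()] or path to a config file.
#' @param objective Path to the objective profile file, or a
#'   `foil_profile`.
#' @param reference Optional path to a reference profile file (or a
#'   `foil_profile`).
#' @param refined_path Optional output path for the refined objective.
#' @return List with `report` (a `flatness_report`), `result` (the
#'   `foilsim_result`) and `refined` (refined objective profile or
#'   `NULL`).
#' @export
design_check <- function(config, objective, reference = NULL,
                         refined_path = NULL) {
  if (is.character(config)) config <- read_config(config)
  res <- run_simulation(config)
  get_prof <- function(x) {
    p <- if (is.character(x)) read_profile_file(x) else x
    stopifnot(inherits(p, "foil_profile"))
    if (max(abs(p$v)) <= 2) p$v <- 100 * p$v   # unit-scale file
    p$normalization <- "percent_of_cax_dmax"
    p
  }
  obj <- get_prof(objective)
  report <- flatness_report(res$total, obj, config$flatness$range,
                            config$flatness$criterion)
  refined <- NULL
  if (!is.null(reference)) {
    ref <- get_prof(reference)
    rng <- config$flatness$range
    r <- res$total$r[abs(res$total$r) <= rng + 1e-12]
    on_grid <- function(p) foil_profile(r, profile_interp(p, r),
                                        "percent_of_cax_dmax")
    refined <- refine_objective(on_grid(obj), on_grid(res$total),
                                on_grid(ref))
    if (!is.null(refined_path))
      write_profile_file(refined, refined_path,
                         header = "refined objective profile")
  }
  list(report = report, result = res, refined = refined)
}
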