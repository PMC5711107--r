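# Total-dose synthesis, flatness evaluation and objective refinement.

#' Off-axis total relative dose profile
#'
#' Combines the off-axis X-ray percent dose and the electron relative
#' dose profile:
#' `DT(r) = %Dgamma(r) + (100 - %Dgamma_CAX) De(r)/De(0)`,
#' normalized so that `DT(0) = 100` exactly.
#'
#' @param electron Electron relative dose `foil_profile` (`"cax_1"`).
#' @param xray_pct X-ray percent dose `foil_profile` on the same grid
#'   (`"percent_of_cax_dmax"`), or `NULL` for an electron-only total.
#' @param cax_xray_pct_at_d Central-axis X-ray percent dose at the
#'   calculation depth, % (0 when `xray_pct` is `NULL`).
#' @return Total dose `foil_profile` (`"cax_100"`).
#' @export
total_dose_profile <- function(electron, xray_pct = NULL,
                               cax_xray_pct_at_d = 0) {
  stopifnot(inherits(electron, "foil_profile"),
            electron$normalization == "cax_1")
  if (!any(electron$r == 0))
    stop("electron profile grid must contain r = 0")
  de <- electron$v / electron$v[electron$r == 0]
  if (is.null(xray_pct)) {
    xr <- 0
    if (cax_xray_pct_at_d != 0)
      stop("cax_xray_pct_at_d must be 0 when no X-ray profile is given")
  } else {
    stopifnot(inherits(xray_pct, "foil_profile"))
    if (length(xray_pct$r) != length(electron$r) ||
        any(abs(xray_pct$r - electron$r) > 1e-9))
      stop("electron and X-ray profiles must share the same radial grid")
    xr <- xray_pct$v
  }
  foil_profile(electron$r, xr + (100 - cax_xray_pct_at_d) * de, "cax_100")
}

#' Flatness evaluation against an objective profile
#'
#' Maximum deviations of a profile above and below an objective profile
#' within a symmetric off-axis range, compared against a flatness
#' criterion. The objective is linearly interpolated onto the profile
#' grid (no extrapolation).
#'
#' @param profile Profile under evaluation (`foil_profile`).
#' @param objective Objective profile (`foil_profile`) covering the
#'   evaluation range; units must match `profile`.
#' @param eval_range Half-range of evaluation, cm (default 14.6: 2 cm
#'   inside the half-diagonal of a 25 x 25 cm^2 applicator field).
#' @param criterion Flatness criterion, same units as the profiles
#'   (default 3, i.e. 3% on a 100-normalized profile).
#' @return Object of class `flatness_report`: `max_over`, `max_under`,
#'   `eval_range`, `criterion`, `passed_over`, `passed_under`.
#' @export
flatness_report <- function(profile, objective, eval_range = 14.6,
                            criterion = 3) {
  stopifnot(inherits(profile, "foil_profile"),
            inherits(objective, "foil_profile"),
            eval_range > 0, criterion >= 0)
  p <- mirror_profile(profile)
  if (min(p$r) > -eval_range + 1e-9 || max(p$r) < eval_range - 1e-9)
    stop(sprintf("evaluation range +/-%.4g cm exceeds the profile support [%.4g, %.4g]",
                 eval_range, min(p$r), max(p$r)))
  sel <- abs(p$r) <= eval_range + 1e-12
  r <- p$r[sel]
  dev <- p$v[sel] - profile_interp(objective, r)
  max_over <- max(0, dev)
  max_under <- max(0, -dev)
  structure(list(max_over = max_over, max_under = max_under,
                 eval_range = eval_range, criterion = criterion,
                 passed_over = max_over <= criterion,
                 passed_under = max_under <= criterion),
            class = "flatness_report")
}

#' @export
print.flatness_report <- function(x, ...) {
  cat(sprintf("<flatness> +%.3g / -%.3g over +/-%.4g cm (criterion %.3g): %s / %s\n",
              x$max_over, x$max_under, x$eval_range, x$criterion,
              if (x$passed_over) "pass" else "FAIL",
              if (x$passed_under) "pass" else "FAIL"))
  invisible(x)
}

#' Refine an objective profile
#'
#' Shifts the objective by the discrepancy between a reference profile
#' (measurement or Monte Carlo) and the analytic simulation:
#' `objective - (reference - simulated)`, pointwise on a common grid.
#' Designing to the refined objective compensates for physics the
#' analytic model does not carry (large-angle and collimator scatter).
#'
#' @param objective,simulated,reference `foil_profile`s on identical
#'   grids.
#' @return The refined objective `foil_profile`.
#' @export
refine_objective <- function(objective, simulated, reference) {
  stopifnot(inherits(objective, "foil_profile"),
            inherits(simulated, "foil_profile"),
            inherits(reference, "foil_profile"))
  same <- function(a, b) length(a$r) == length(b$r) &&
    all(abs(a$r - b$r) < 1e-9)
  if (!same(objective, simulated) || !same(objective, reference))
    stop("objective, simulated and reference profiles must share one grid")
  v <- objective$v - (reference$v - simulated$v)
  # the refinement generally moves the central-axis value, so a strict
  # cax tag no longer applies to the result
  tag <- objective$normalization
  if (tag %in% c("cax_1", "cax_100") && any(objective$r == 0) &&
      abs(v[objective$r == 0] - if (tag == "cax_1") 1 else 100) > 1e-9)
    tag <- "percent_of_cax_dmax"
  foil_profile(objective$r, v, tag)
}
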