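# Bremsstrahlung contamination model: per-element X-ray budget, off-axis
# relative dose via exponential-integral brackets, and the semi-empirical
# central-axis percent-dose calibration.

#' Exponential integral E1
#'
#' Standard exponential integral `E1(x) = int_x^inf exp(-u)/u du` for
#' `x > 0`.
#'
#' @param x Positive values (vectorized).
#' @return `E1(x)`.
#' @export
#' @examples
#' exp_integral_E1(1)
exp_integral_E1 <- function(x) {
  if (any(x <= 0)) stop("exp_integral_E1 requires x > 0")
  vapply(x, pracma::expint_E1, 0)
}

#' Empirical incident-beam scattering moment
#'
#' The zeroth-order scattering moment assigned to the beam incident on
#' the vacuum window, `A00 = 0.05 E^-1.6` (E in MeV): a semi-empirical
#' stand-in for the forward peaking of the bremsstrahlung emission that
#' keeps the r = 0 limit of the off-axis X-ray model finite.
#'
#' @param E Incident electron energy, MeV (vectorized).
#' @return `A00` (rad^2 scale).
#' @export
#' @examples
#' a00_empirical(1)   # 0.05
a00_empirical <- function(E) {
  stopifnot(all(E > 0))
  0.05 * E^(-1.6)
}

#' Central-axis X-ray calibration constants
#'
#' Constants of the fitted central-axis percent-dose relation
#' `%D = a X + b (1 - exp(-c X))`.
#'
#' @param a Linear coefficient, % per MeV (default -0.035).
#' @param b Saturation level, % (default 15.77).
#' @param c Exponential rate, 1/MeV (default 0.016).
#' @return Object of class `xray_calibration`.
#' @export
xray_calibration <- function(a = -0.035, b = 15.77, c = 0.016) {
  structure(list(a = a, b = b, c = c), class = "xray_calibration")
}

#' Per-element X-ray budget
#'
#' Radiative energy loss, scattering power, mean thickness and entrance
#' zeroth moment for each scattering element (vacuum window, primary
#' foil, secondary foil). The entrance moments chain as
#' `A0_[i+1] = A0_i + T_i t_i` starting from the empirical incident
#' moment [a00_empirical()]. Scattering powers and radiative losses are
#' evaluated at each element's mean entrance energy.
#'
#' @param window,primary Lists with `material` and `thickness` (cm).
#' @param foil A `segmented_foil`, or `NULL` (no secondary foil).
#' @param energies Energy schedule as produced by the transport setup:
#'   needs `E_incident`, `E_primary_in`, `E_secondary_in`.
#' @param incident_fluence Half-grid fluence profile at z1 (weights for
#'   the mean secondary thickness).
#' @param t_secondary One of `"fluence_weighted"` (default: mean local
#'   thickness weighted by the incident fluence) or `"cax"` (central-axis
#'   thickness).
#' @return Object of class `xray_budget`: a data frame with columns
#'   `element`, `dE_rad` (MeV), `T` (rad^2/cm), `t` (cm), `A0_entry`
#'   (rad^2), and attribute `A00`.
#' @export
build_xray_budget <- function(window, primary, foil, energies,
                              incident_fluence = NULL,
                              t_secondary = c("fluence_weighted", "cax")) {
  t_secondary <- match.arg(t_secondary)
  A00 <- a00_empirical(energies$E_incident)

  el_names <- c("window", "primary", "secondary")
  mats <- list(get_material(window$material), get_material(primary$material),
               if (!is.null(foil)) foil$material)
  th <- c(window$thickness, primary$thickness, 0)
  Ein <- c(energies$E_incident, energies$E_primary_in,
           energies$E_secondary_in)
  if (!is.null(foil)) {
    th[3] <- if (t_secondary == "cax") local_thickness(foil, 0) else {
      if (is.null(incident_fluence))
        stop("incident_fluence required for the fluence-weighted mean thickness")
      keep <- incident_fluence$r >= 0
      r <- incident_fluence$r[keep]; v <- incident_fluence$v[keep]
      w <- v * r
      if (sum(w) == 0) w <- v
      sum(w * local_thickness(foil, r)) / sum(w)
    }
  }
  n <- if (is.null(foil)) 2L else 3L
  dE <- Tt <- numeric(n)
  for (i in seq_len(n)) {
    if (th[i] > 0) {
      dE[i] <- radiative_mass_stopping_power(mats[[i]], Ein[i]) *
        mats[[i]]$density * th[i]
      Tt[i] <- reduced_gaussian_scattering_power(mats[[i]], th[i], Ein[i])$T
    }
  }
  A0 <- A00 + c(0, cumsum((Tt * th[seq_len(n)])[-n]))
  b <- data.frame(element = el_names[seq_len(n)], dE_rad = dE, T = Tt,
                  t = th[seq_len(n)], A0_entry = A0)
  attr(b, "A00") <- A00
  class(b) <- c("xray_budget", "data.frame")
  b
}

# bracket sum at a given (r/z)^2; theta2 = 0 uses the logarithmic limit
.budget_bracket_sum <- function(budget, theta2) {
  s <- 0
  for (i in seq_len(nrow(budget))) {
    Tt <- budget$T[i] * budget$t[i]
    if (Tt <= 0) next                       # zero-thickness element
    A0 <- budget$A0_entry[i]
    br <- if (theta2 == 0) log1p(Tt / A0) else
      exp_integral_E1(theta2 / (A0 + Tt)) - exp_integral_E1(theta2 / A0)
    s <- s + budget$dE_rad[i] / Tt * br
  }
  s
}

#' Off-axis X-ray relative dose
#'
#' Ratio of the off-axis bremsstrahlung dose at radius `r` on a plane a
#' distance `z` from the virtual source to its central-axis value: the
#' summed per-element exponential-integral brackets at `(r/z)^2`,
#' normalized by the analytic `r = 0` logarithmic limit.
#'
#' @param budget An `xray_budget`.
#' @param z Distance from the virtual source (z = 0), cm.
#' @param r Off-axis distance, cm (vectorized, >= 0 or mirrored via
#'   `abs`).
#' @return Relative dose in (0, 1]; exactly 1 at r = 0.
#' @export
offaxis_xray_relative <- function(budget, z, r) {
  stopifnot(inherits(budget, "xray_budget"), z > 0)
  denom <- .budget_bracket_sum(budget, 0)
  vapply(abs(r), function(ri)
    .budget_bracket_sum(budget, (ri / z)^2) / denom, 0)
}

#' Practical range of an electron beam in water
#'
#' Uses the 2 MeV/cm rule: `Rp = Ep0 / 2`.
#'
#' @param Ep0 Most probable surface energy, MeV.
#' @return Practical range, cm.
#' @export
practical_range <- function(Ep0) {
  stopifnot(all(Ep0 > 0))
  Ep0 / 2
}

#' X-ray calibration statistic X(E)
#'
#' The semi-empirical predictor of the central-axis X-ray percent dose:
#' inverse-square factor at depth `Rp + 2` times the summed central-axis
#' brackets, divided by the per-electron central-axis electron fluence at
#' the calculation plane.
#'
#' @param budget An `xray_budget`.
#' @param cax_fluence Un-normalized per-electron central-axis planar
#'   fluence at z2, 1/cm^2 (> 0).
#' @param Rp Practical range, cm.
#' @param SAD Source-to-axis distance, cm (default 100).
#' @return `X`, MeV.
#' @export
x_statistic <- function(budget, cax_fluence, Rp, SAD = 100) {
  stopifnot(inherits(budget, "xray_budget"))
  if (!(cax_fluence > 0)) stop("central-axis fluence must be > 0")
  .budget_bracket_sum(budget, 0) / ((SAD + Rp + 2)^2 * cax_fluence)
}

#' Central-axis X-ray percent dose at depth Rp + 2
#'
#' Fitted relation `%D = a X + b (1 - exp(-c X))`, forced through the
#' origin. A negative result (possible far outside the fitted X range)
#' is clamped to zero with a warning.
#'
#' @param X Calibration statistic, MeV (>= 0).
#' @param cal An [xray_calibration()].
#' @return Percent of the central-axis dose maximum.
#' @export
cax_xray_percent <- function(X, cal = xray_calibration()) {
  stopifnot(inherits(cal, "xray_calibration"), all(X >= 0))
  v <- cal$a * X + cal$b * (1 - exp(-cal$c * X))
  if (any(v < 0)) {
    warning("central-axis X-ray percent dose clamped at 0 (X outside the fitted range)")
    v <- pmax(v, 0)
  }
  v
}

#' Rescale the central-axis X-ray percent dose to another depth
#'
#' Inverse-square rescaling from the reference depth `Rp + 2` to depth
#' `d` (X-ray attenuation in water is deliberately ignored).
#'
#' @param pct_at_Rp2 Percent dose at depth `Rp + 2`.
#' @param Rp Practical range, cm.
#' @param d Target depth, cm (>= 0).
#' @param SAD Source-to-axis distance, cm.
#' @return Percent dose at depth `d`.
#' @export
cax_xray_percent_at_depth <- function(pct_at_Rp2, Rp, d, SAD = 100) {
  stopifnot(d >= 0)
  pct_at_Rp2 * ((SAD + Rp + 2) / (SAD + d))^2
}

#' Off-axis X-ray percent dose profile
#'
#' Product of the off-axis relative X-ray dose (evaluated on a plane
#' `SAD + d` from the virtual source) and the central-axis percent dose
#' rescaled to depth `d`.
#'
#' @param budget An `xray_budget`.
#' @param cal An [xray_calibration()].
#' @param geometry A `beamline_geometry` (supplies `SAD` and depth `d`).
#' @param Ep0 Most probable surface energy, MeV.
#' @param cax_fluence Per-electron central-axis fluence at z2, 1/cm^2.
#' @param r Radial grid, cm (may be symmetric about 0).
#' @return A `foil_profile` (`"percent_of_cax_dmax"`) with attributes
#'   `X`, `cax_pct_Rp2` and `cax_pct_at_d`.
#' @export
offaxis_xray_percent_profile <- function(budget, cal, geometry, Ep0,
                                         cax_fluence, r) {
  stopifnot(inherits(geometry, "beamline_geometry"))
  Rp <- practical_range(Ep0)
  d <- geometry$calc_depth
  X <- x_statistic(budget, cax_fluence, Rp, geometry$SAD)
  pct_Rp2 <- cax_xray_percent(X, cal)
  pct_d <- cax_xray_percent_at_depth(pct_Rp2, Rp, d, geometry$SAD)
  rel <- offaxis_xray_relative(budget, geometry$SAD + d, r)
  p <- foil_profile(r, rel * pct_d, "percent_of_cax_dmax")
  attr(p, "X") <- X
  attr(p, "cax_pct_Rp2") <- pct_Rp2
  attr(p, "cax_pct_at_d") <- pct_d
  p
}
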