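# Fermi-Eyges moment accumulation and the pencil-beam convolution.
#
# Moments convention: T is the full-plane mean-square-angle growth rate
# (rad^2/cm), so at a reference plane z_ref
#   A_n(z_ref) = sum_i integral T_i (z_ref - z')^n dz'
# and the radial spatial variance is sigma_r^2 = A2 (per-axis variance
# A2/2). Mean pencil directions emanate from z = 0 (top of the primary
# foil): a pencil at radius rho on the secondary-foil plane z1 projects
# to (z2/z1) rho on the calculation plane z2.

#' Describe one beamline scatterer
#'
#' @param material Material name or `foil_material` (ignored when an
#'   explicit `T` is given).
#' @param thickness Slab thickness, cm.
#' @param z_start Axial position of the upstream face, cm (z = 0 at the
#'   top of the primary foil).
#' @param E Mean kinetic energy entering the element, MeV (used to
#'   evaluate the reduced-Gaussian scattering power).
#' @param T Optional explicit scattering power, rad^2/cm; bypasses the
#'   Moliere evaluation (used in tests and for custom elements).
#' @return A `beamline_element` list.
#' @export
beamline_element <- function(material = NULL, thickness, z_start, E = NULL,
                             T = NULL) {
  stopifnot(thickness >= 0)
  if (is.null(T)) {
    stopifnot(!is.null(material), !is.null(E))
    T <- if (thickness > 0)
      reduced_gaussian_scattering_power(material, thickness, E)$T else 0
  }
  structure(list(material = material, thickness = thickness,
                 z_start = z_start, E = E, T = T),
            class = "beamline_element")
}

#' Accumulate Fermi-Eyges scattering moments
#'
#' Sums per-element moment contributions at a downstream reference plane,
#' integrating the (piecewise-constant) scattering power over each
#' element's extent: `A0 += T t`, `A1 += T t m` and
#' `A2 += T t (m^2 + t^2/12)` with `m` the distance from the element
#' midpoint to the reference plane -- the exact integrals, reducing to
#' the familiar `T t (z_ref - z_mid)^n` for thin foils.
#'
#' @param elements List of [beamline_element()]s ordered upstream to
#'   downstream.
#' @param z_ref Reference plane, cm; every element must lie upstream.
#' @return Object of class `scattering_moments`: numeric `A0` (rad^2),
#'   `A1` (rad^2 cm), `A2` (rad^2 cm^2).
#' @export
accumulate_moments <- function(elements, z_ref) {
  A <- c(A0 = 0, A1 = 0, A2 = 0)
  for (el in elements) {
    z_end <- el$z_start + el$thickness
    if (z_end > z_ref + 1e-9)
      stop(sprintf("element at z = [%.4g, %.4g] cm lies downstream of the reference plane z = %.4g cm",
                   el$z_start, z_end, z_ref))
    t <- el$thickness
    m <- z_ref - el$z_start - t / 2    # distance to the element midpoint
    A["A0"] <- A["A0"] + el$T * t
    A["A1"] <- A["A1"] + el$T * t * m
    A["A2"] <- A["A2"] + el$T * t * (m^2 + t^2 / 12)
  }
  structure(as.list(A), class = "scattering_moments")
}

#' @export
print.scattering_moments <- function(x, ...) {
  cat(sprintf("<moments> A0 = %.4g rad^2, A1 = %.4g rad^2 cm, A2 = %.4g rad^2 cm^2\n",
              x$A0, x$A1, x$A2))
  invisible(x)
}

#' Incident electron fluence at the secondary-foil plane
#'
#' Planar fluence per incident electron at z1: a radial Gaussian
#' `Phi(rho) = exp(-rho^2 / A2) / (pi A2)` with `sigma_r^2 = A2`, which
#' integrates to one over the plane.
#'
#' @param moments A `scattering_moments` at z1 with `A2 > 0`.
#' @param n Number of radial grid points (default 201).
#' @param r_max Outer radius of the grid, cm; defaults to `5 sigma_r`.
#' @return A half-grid `foil_profile` (normalization
#'   `"absolute_per_electron"`) with attribute `A2`.
#' @export
incident_fluence_z1 <- function(moments, n = 201, r_max = NULL) {
  stopifnot(inherits(moments, "scattering_moments"))
  A2 <- moments$A2
  if (A2 <= 0)
    stop("A2 = 0: unscattered (delta) beam has no Gaussian fluence; ",
         "use the analytic no-secondary-foil path")
  if (is.null(r_max)) r_max <- 5 * sqrt(A2)
  r <- seq(0, r_max, length.out = n)
  p <- foil_profile(r, exp(-r^2 / A2) / (pi * A2), "absolute_per_electron")
  attr(p, "A2") <- A2
  p
}

#' Fluence-weighted mean exit energy of the secondary foil
#'
#' Exit energies are computed per integration radius from the local foil
#' thickness and averaged with annular fluence weights
#' `Phi(rho) rho drho`. The scattering power of the secondary foil is
#' evaluated at the average of the mean entrance energy and this result.
#'
#' @param foil A `segmented_foil`.
#' @param incident_fluence Half-grid `foil_profile` of the incident
#'   fluence at z1 (its radial grid is the integration grid).
#' @param E_in Mean kinetic energy entering the foil, MeV.
#' @return Fluence-weighted mean exit energy, MeV.
#' @export
secondary_exit_mean_energy <- function(foil, incident_fluence, E_in) {
  stopifnot(inherits(foil, "segmented_foil"),
            inherits(incident_fluence, "foil_profile"))
  keep <- incident_fluence$r >= 0
  r <- incident_fluence$r[keep]
  v <- incident_fluence$v[keep]
  if (all(v == 0)) stop("incident fluence is identically zero")
  w <- v * r
  if (sum(w) == 0) {  # degenerate grid (single axis point)
    w <- v
  }
  t_loc <- local_thickness(foil, r)
  E_exit <- vapply(unique(t_loc), function(t)
    if (t == 0) E_in else mean_energy_after(foil$material, t, E_in), 0)
  names(E_exit) <- as.character(unique(t_loc))
  sum(w * E_exit[as.character(t_loc)]) / sum(w)
}

#' Pencil-beam kernel variance at the calculation plane
#'
#' Full-plane spatial variance at z2 of the pencil incident at radius
#' `rho` on the secondary-foil plane z1:
#' upstream angular spread carried over the drift (conditional variance
#' `A0 - A1^2/A2`, removing the position-angle correlation already spent
#' in the spatial spread at z1), plus the local secondary-foil scatter
#' `T_sec t(rho) (z2-z1)^2`, plus the air scatter accumulated between z1
#' and z2.
#'
#' @param rho Pencil radius at z1, cm (vectorized).
#' @param foil A `segmented_foil`, or `NULL` for no secondary foil.
#' @param geometry A `beamline_geometry`.
#' @param moments_z1 Upstream `scattering_moments` at z1.
#' @param E_sec Energy for the secondary-foil scattering power, MeV
#'   (average of mean entrance and fluence-weighted exit energies).
#' @param kernel `"conditional"` (default) or `"uncorrelated"` (uses the
#'   raw `A0` instead of the conditional angular variance).
#' @param E_air Energy for the z1 to z2 air scattering power, MeV
#'   (defaults to `E_sec`).
#' @return Variance sigma^2, cm^2 (full-plane convention).
#' @export
pencil_kernel_variance <- function(rho, foil, geometry, moments_z1, E_sec,
                                   kernel = c("conditional", "uncorrelated"),
                                   E_air = E_sec) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(geometry, "beamline_geometry"), all(rho >= 0))
  L <- geometry$z2 - geometry$z1
  ang <- if (kernel == "conditional" && moments_z1$A2 > 0)
    moments_z1$A0 - moments_z1$A1^2 / moments_z1$A2 else moments_z1$A0
  base <- ang * L^2
  air <- reduced_gaussian_scattering_power("air", L, E_air)$T * L^3 / 3
  sec <- numeric(length(rho))
  if (!is.null(foil)) {
    t_loc <- local_thickness(foil, rho)
    t_floor <- .min_positive_thickness(foil)
    for (t in unique(t_loc[t_loc > 0])) {
      Tt <- reduced_gaussian_scattering_power(foil$material,
                                              max(t, t_floor), E_sec)$T
      sec[t_loc == t] <- Tt * t * L^2
    }
  }
  base + sec + air
}

# ---- full transport setup -------------------------------------------------

# assemble the upstream element stack (window, air, primary, air) with the
# mean-energy schedule, the moments and incident fluence at z1, and the
# secondary-foil energies
.build_transport <- function(config) {
  config <- validate_config(config)
  geom <- do.call(beamline_geometry, config$geometry)
  win_mat <- get_material(config$window$material)
  pri_mat <- get_material(config$primary_foil$material)
  air <- get_material("air")
  t_w <- config$window$thickness
  t_p <- config$primary_foil$thickness

  E_i <- if (config$beam$mode == "incident_mean") config$beam$energy else
    solve_incident_energy(config)

  E_w_exit <- mean_energy_after(win_mat, t_w, E_i)
  E_p_in <- mean_energy_after(air, geom$d_window_primary, E_w_exit)
  E_p_exit <- mean_energy_after(pri_mat, t_p, E_p_in)
  E_s_in <- mean_energy_after(air, geom$z1, E_p_exit)

  elements <- list(
    beamline_element(win_mat, t_w, geom$z_window, E_i),
    beamline_element(air, geom$d_window_primary, geom$z_window, E_w_exit),
    beamline_element(pri_mat, t_p, 0, E_p_in),
    beamline_element(air, geom$z1, 0, E_p_exit))
  moments_z1 <- accumulate_moments(elements, geom$z1)
  fluence_z1 <- incident_fluence_z1(moments_z1)

  foil <- switch(config$secondary_foil$mode,
    none = NULL,
    file = load_secondary_foil_file(config$secondary_foil$file),
    gaussian = segment_gaussian_foil(gaussian_foil_spec(
      config$secondary_foil$material, config$secondary_foil$t0,
      config$secondary_foil$sigma, config$secondary_foil$n_segments,
      config$secondary_foil$r_max)))

  if (!is.null(foil)) {
    E_s_exit <- secondary_exit_mean_energy(foil, fluence_z1, E_s_in)
    E_s_scatter <- (E_s_in + E_s_exit) / 2
  } else {
    E_s_exit <- E_s_in
    E_s_scatter <- E_s_in
  }
  E0_mean <- mean_energy_after(air, geom$d_secondary_iso, E_s_exit)
  Ep0 <- E0_mean + config$beam$ep0_offset

  list(config = config, geometry = geom, elements = elements,
       moments_z1 = moments_z1, fluence_z1 = fluence_z1, foil = foil,
       energies = list(E_incident = E_i, E_window_exit = E_w_exit,
                       E_primary_in = E_p_in, E_primary_exit = E_p_exit,
                       E_secondary_in = E_s_in, E_secondary_exit = E_s_exit,
                       E_secondary_scatter = E_s_scatter,
                       E0_mean = E0_mean, Ep0 = Ep0))
}

#' Solve for the incident energy from a surface energy
#'
#' Backward energy mode: given the most probable energy at the surface
#' `Ep0` (minus the configured display offset, giving the mean surface
#' energy), finds the monoenergetic incident energy whose forward
#' transport through the beamline reproduces it.
#'
#' @param config A simulation configuration with
#'   `beam$mode = "surface_Ep0"`.
#' @return Incident mean energy, MeV.
#' @export
solve_incident_energy <- function(config) {
  target <- config$beam$energy - config$beam$ep0_offset
  if (target <= 0) stop("surface energy must exceed the Ep0 display offset")
  fwd <- function(E_i) {
    cfg <- config
    cfg$beam$mode <- "incident_mean"
    cfg$beam$energy <- E_i
    .build_transport(cfg)$energies$E0_mean - target
  }
  stats::uniroot(fwd, c(target + 1e-6, target + 10), tol = 1e-8,
                 extendInt = "upX")$root
}

# ---- the Eq.-style convolution -------------------------------------------

# analytic no-secondary path: project the full upstream stack to z2
.gaussian_profile_z2 <- function(config, setup) {
  geom <- setup$geometry
  air <- get_material("air")
  elements <- list(
    setup$elements[[1]],                             # window
    setup$elements[[2]],                             # air window->primary
    setup$elements[[3]],                             # primary
    beamline_element(air, geom$z2, 0, setup$energies$E_primary_exit))
  m <- accumulate_moments(elements, geom$z2)
  list(A2 = m$A2, moments_z2 = m)
}

#' Off-axis electron fluence profile at the calculation plane
#'
#' Convolves the incident Gaussian fluence at the secondary-foil plane
#' with per-pencil Gaussian kernels by polar double quadrature (midpoint
#' rule in radius and angle). Each pencil at radius `rho` carries weight
#' `Phi(z1, rho) rho drho dTheta`, projects to `(z2/z1) rho`, and spreads
#' with [pencil_kernel_variance()]. With no secondary foil the analytic
#' projected Gaussian is returned instead.
#'
#' @param config A simulation configuration (see [simulation_config()]).
#' @param setup Optional precomputed transport setup (internal reuse).
#' @param check_convergence Logical; when `TRUE` the quadrature is
#'   repeated with doubled point counts and a warning is issued if the
#'   central-axis value moves by more than 0.5%.
#' @return A symmetric-grid `foil_profile` (`"cax_1"`), with attributes
#'   `cax_absolute` (per-electron planar fluence at r = 0, 1/cm^2),
#'   `transport` (energy schedule and moments) and, for the analytic
#'   path, `sigma_r` (cm).
#' @export
electron_fluence_profile <- function(config, setup = NULL,
                                     check_convergence = FALSE) {
  if (is.null(setup)) setup <- .build_transport(config)
  config <- setup$config
  calc <- config$calculation
  r_half <- seq(0, calc$half_range, length.out = calc$n_profile)

  if (is.null(setup$foil)) {
    g <- .gaussian_profile_z2(config, setup)
    v <- exp(-r_half^2 / g$A2)
    p <- mirror_profile(foil_profile(r_half, v, "cax_1"))
    attr(p, "cax_absolute") <- 1 / (pi * g$A2)
    attr(p, "sigma_r") <- sqrt(g$A2)
    attr(p, "transport") <- setup[c("energies", "moments_z1")]
    return(p)
  }

  quad <- function(n_rho, n_theta) {
    .polar_convolution(r_half, setup, n_rho, n_theta)
  }
  v_abs <- quad(calc$n_rho, calc$n_theta)
  if (check_convergence) {
    v2 <- quad(2L * calc$n_rho, 2L * calc$n_theta)
    rel <- abs(v2[1] - v_abs[1]) / v2[1]
    if (rel > 0.005)
      warning(sprintf("quadrature not converged: doubling the integration points moves the central-axis value by %.2f%%",
                      100 * rel))
  }
  p <- mirror_profile(foil_profile(r_half, v_abs / v_abs[1], "cax_1"))
  attr(p, "cax_absolute") <- v_abs[1]
  attr(p, "transport") <- setup[c("energies", "moments_z1")]
  p
}

# midpoint-rule polar quadrature of the pencil convolution; returns the
# absolute per-electron planar fluence on the half grid r_half
.polar_convolution <- function(r_half, setup, n_rho, n_theta) {
  geom <- setup$geometry
  A2 <- setup$moments_z1$A2
  cfg <- setup$config
  # integrate far enough to capture the incident Gaussian even when it
  # extends beyond the physical foil radius (thickness is zero there)
  rho_max <- max(max(setup$foil$boundaries), 4 * sqrt(A2))
  d_rho <- rho_max / n_rho
  rho <- (seq_len(n_rho) - 0.5) * d_rho
  d_th <- pi / n_theta
  theta <- (seq_len(n_theta) - 0.5) * d_th
  cth <- cos(theta)
  proj <- geom$z2 / geom$z1
  sig2 <- pencil_kernel_variance(rho, setup$foil, geom, setup$moments_z1,
                                 setup$energies$E_secondary_scatter,
                                 kernel = cfg$calculation$kernel)
  phi1 <- exp(-rho^2 / A2) / (pi * A2)
  w <- phi1 * rho * d_rho * d_th * 2     # theta symmetry: [0, pi] doubled
  out <- numeric(length(r_half))
  for (k in seq_len(n_rho)) {
    mu <- proj * rho[k]
    # |r - mu|^2 = r^2 + mu^2 - 2 r mu cos(theta); rows index r
    q <- (r_half^2 + mu^2) - 2 * mu * outer(r_half, cth)
    out <- out + (w[k] / (pi * sig2[k])) *
      rowSums(exp(-q / sig2[k]))
  }
  out
}

#' Electron relative dose profile
#'
#' Converts a relative fluence profile to a relative dose profile. The
#' conversion factor is the water collision mass stopping power at
#' `Ed = Ep0 - 2 d` (the mean depth-degraded energy at 2 MeV/cm), which
#' is constant across the profile under the assumption of an off-axis
#' invariant spectrum -- so the relative profile is unchanged and the
#' factor is reported as an attribute.
#'
#' @param fluence A `"cax_1"` `foil_profile`.
#' @param Ep0 Most probable energy at the surface, MeV.
#' @param d Calculation depth, cm.
#' @return The relative dose `foil_profile` (`"cax_1"`) with attributes
#'   `Ke` (MeV cm^2/g) and `Ed` (MeV).
#' @export
electron_dose_profile <- function(fluence, Ep0, d) {
  stopifnot(inherits(fluence, "foil_profile"),
            fluence$normalization == "cax_1")
  Ed <- Ep0 - 2 * d
  if (Ed <= 0)
    stop(sprintf("calculation depth %.3g cm is beyond practical range for Ep0 = %.3g MeV",
                 d, Ep0))
  p <- foil_profile(fluence$r, fluence$v, "cax_1")
  attr(p, "Ke") <- collision_mass_stopping_power("water", Ed)
  attr(p, "Ed") <- Ed
  attr(p, "cax_absolute") <- attr(fluence, "cax_absolute")
  p
}
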