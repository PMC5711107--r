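# Independent oracles used across the test suite. These deliberately do
# not call the package code paths they check.

# ---- exponential integral E1 ---------------------------------------------
# power series for x <= 1, modified-Lentz continued fraction for x > 1

e1_oracle <- function(x) {
  vapply(x, function(xi) {
    if (xi <= 1) {
      s <- -0.57721566490153286 - log(xi)
      term <- 1
      for (k in 1:60) {
        term <- term * (-xi) / k
        s <- s - term / k
        if (abs(term / k) < 1e-18) break
      }
      s
    } else {
      # E1(x) = exp(-x)/(x+1 - 1/(x+3 - 4/(x+5 - 9/(x+7 - ...)))),
      # evaluated by backward recurrence
      cf <- 0
      for (k in 160:1) cf <- k^2 / (xi + 2 * k + 1 - cf)
      exp(-xi) / (xi + 1 - cf)
    }
  }, 0)
}

# ---- second, independent coding of the stopping-power formulas -----------
# written against the published formulas in a different algebraic
# arrangement from the package implementation

scol_oracle <- function(Z_A, I_eV, E, delta = 0) {
  mec2 <- 0.51099895
  k0 <- 0.1535363  # 2 pi re^2 mec2 NA (4-digit constant is enough here)
  g <- E / mec2 + 1
  b2 <- (g^2 - 1) / g^2
  tau <- g - 1
  f <- 1 - b2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / g^2
  lg <- 2 * log(mec2 * 1e6 / I_eV) + log(tau^2 * (tau + 2) / 2)
  k0 * Z_A / b2 * (lg + f - delta)
}

# exact water density effect, recoded: bisection instead of uniroot
delta_water_oracle <- function(E) {
  f <- c(2, 2, 2, 4) / 10
  Eb <- c(13.6, 538.0, 28.48, 13.62)
  hwp <- 28.8159 * sqrt(1 * 7.42 / 13.3671)
  target <- log(75)
  gmu <- function(mu) sum(f * 0.5 * log((mu * Eb)^2 + (2 / 3) * f * hwp^2)) -
    target
  lo <- 0.1; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (gmu(mid) > 0) hi <- mid else lo <- mid
  }
  li2 <- (((lo + hi) / 2 * Eb) / hwp)^2 + (2 / 3) * f
  vapply(E, function(e) {
    g <- e / 0.51099895 + 1
    rhs <- 1 / g^2
    if (sum(f / li2) <= rhs) return(0)
    a <- 0; b <- 1e14
    h <- function(l2) sum(f / (li2 + l2)) - rhs
    for (i in 1:220) {
      m <- (a + b) / 2
      if (h(m) > 0) a <- m else b <- m
    }
    l2 <- (a + b) / 2
    sum(f * log(1 + l2 / li2)) - l2 * rhs
  }, 0)
}

srad_oracle <- function(Z, A, E) {
  mec2 <- 0.51099895
  alpha <- 1 / 137.035999
  re <- 2.8179403262e-13
  NAv <- 6.02214076e23
  Et <- E + mec2
  az2 <- (alpha * Z)^2
  fc <- az2 * (1 / (1 + az2) + 0.20206 - 0.0369 * az2 + 0.0083 * az2^2 -
                 0.002 * az2^3)
  b_free <- 4 * log(2 * Et / mec2) - 4 / 3
  b_full <- 4 * (Z^2 * (log(184.15 / Z^(1 / 3)) - fc) +
                   Z * log(1194 / Z^(2 / 3))) / (Z * (Z + 1))
  alpha * re^2 * NAv * Z * (Z + 1) / A * Et * min(b_free, b_full)
}

# ---- Monte Carlo random-walk transport oracle ----------------------------
# Per-axis Gaussian random walk through the thin-element stack of a
# configuration: kicks with per-axis variance T t / 2, drifts between,
# air gaps as 10 sub-slabs. Returns positions/angles at z1 and
# positions at z2. Uses the package only for scattering powers and the
# energy schedule (both tested independently); the transport itself --
# the quantity under test -- is simulated, not computed.

mc_walk <- function(config, n = 2e5) {
  geom <- beamline_geometry(config$geometry$d_window_primary,
                            config$geometry$d_primary_secondary,
                            config$geometry$d_secondary_iso,
                            calc_depth = config$geometry$calc_depth)
  win <- get_material(config$window$material)
  pri <- get_material(config$primary_foil$material)
  air <- get_material("air")
  Ei <- config$beam$energy
  t_w <- config$window$thickness
  t_p <- config$primary_foil$thickness
  Ew <- mean_energy_after(win, t_w, Ei)
  Ep_in <- mean_energy_after(air, geom$d_window_primary, Ew)
  Ep_ex <- mean_energy_after(pri, t_p, Ep_in)
  Es_in <- mean_energy_after(air, geom$z1, Ep_ex)

  x <- y <- tx <- ty <- numeric(n)
  kick2 <- function(var_axis) {
    tx <<- tx + stats::rnorm(n, 0, sqrt(var_axis))
    ty <<- ty + stats::rnorm(n, 0, sqrt(var_axis))
  }
  drift <- function(L) { x <<- x + tx * L; y <<- y + ty * L }
  air_gap <- function(L, E) {
    Tair <- reduced_gaussian_scattering_power(air, L, E)$T
    for (i in 1:10) { drift(L / 10); kick2(Tair * L / 10 / 2) }
  }
  kick2(reduced_gaussian_scattering_power(win, t_w, Ei)$T * t_w / 2)
  air_gap(geom$d_window_primary, Ew)
  kick2(reduced_gaussian_scattering_power(pri, t_p, Ep_in)$T * t_p / 2)
  air_gap(geom$z1, Ep_ex)
  x1 <- x; y1 <- y; tx1 <- tx; ty1 <- ty

  foil <- switch(config$secondary_foil$mode,
                 none = NULL,
                 gaussian = segment_gaussian_foil(gaussian_foil_spec(
                   config$secondary_foil$material, config$secondary_foil$t0,
                   config$secondary_foil$sigma,
                   config$secondary_foil$n_segments,
                   config$secondary_foil$r_max)))
  E_air3 <- Es_in
  if (!is.null(foil)) {
    m1 <- accumulate_moments(list(
      beamline_element(win, t_w, geom$z_window, Ei),
      beamline_element(air, geom$d_window_primary, geom$z_window, Ew),
      beamline_element(pri, t_p, 0, Ep_in),
      beamline_element(air, geom$z1, 0, Ep_ex)), geom$z1)
    Es_ex <- secondary_exit_mean_energy(foil, incident_fluence_z1(m1), Es_in)
    Es <- (Es_in + Es_ex) / 2
    tloc <- local_thickness(foil, sqrt(x^2 + y^2))
    v <- numeric(n)
    for (t in unique(tloc[tloc > 0]))
      v[tloc == t] <-
        reduced_gaussian_scattering_power(foil$material, t, Es)$T * t / 2
    tx <- tx + stats::rnorm(n, 0, sqrt(v))
    ty <- ty + stats::rnorm(n, 0, sqrt(v))
    E_air3 <- Es
  }
  air_gap(geom$z2 - geom$z1, E_air3)
  data.frame(x1 = x1, y1 = y1, tx1 = tx1, ty1 = ty1,
             x2 = x, y2 = y,
             r1 = sqrt(x1^2 + y1^2), r2 = sqrt(x^2 + y^2))
}

# ---- dense Cartesian convolution oracle ----------------------------------
# Brute-force evaluation of the pencil convolution on a Cartesian z1
# grid, for a handful of output radii. Uses the same physical inputs
# (incident Gaussian, projection, kernel variances) as the polar
# quadrature under test, but an entirely different integration scheme.

cartesian_convolution <- function(config, r_out, n_grid = 321) {
  setup <- foilsim:::.build_transport(config)
  geom <- setup$geometry
  A2 <- setup$moments_z1$A2
  half <- max(max(setup$foil$boundaries), 4 * sqrt(A2))
  xs <- seq(-half, half, length.out = n_grid)
  dA <- diff(xs)[1]^2
  g <- expand.grid(px = xs, py = xs)
  rho <- sqrt(g$px^2 + g$py^2)
  phi1 <- exp(-rho^2 / A2) / (pi * A2)
  sig2 <- pencil_kernel_variance(rho, setup$foil, geom, setup$moments_z1,
                                 setup$energies$E_secondary_scatter,
                                 kernel = config$calculation$kernel)
  proj <- geom$z2 / geom$z1
  vapply(r_out, function(r0) {
    d2 <- (r0 - proj * g$px)^2 + (proj * g$py)^2
    sum(phi1 / (pi * sig2) * exp(-d2 / sig2)) * dA
  }, 0)
}

# ---- shared fixtures ------------------------------------------------------

# fast toy configuration: coarser quadrature and profile grids
toy_config <- function(...) {
  cfg <- simulation_config(...)
  cfg$calculation$n_rho <- 50
  cfg$calculation$n_theta <- 50
  cfg$calculation$n_profile <- 31
  cfg$secondary_foil$n_segments <- 12
  cfg
}
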