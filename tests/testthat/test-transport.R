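# Fermi-Eyges moments, incident fluence, kernel variance and the
# pencil-beam convolution.

test_that("moment accumulation: empty stack, thin-scatterer closed form, additivity", {
  m0 <- accumulate_moments(list(), 15)
  expect_equal(c(m0$A0, m0$A1, m0$A2), c(0, 0, 0))

  el <- beamline_element(thickness = 1e-9, z_start = 0, T = 2e7)
  m <- accumulate_moments(list(el), 15)
  Tt <- 2e7 * 1e-9
  expect_equal(m$A0, Tt, tolerance = 1e-9)
  expect_equal(m$A1, Tt * 15, tolerance = 1e-6)
  expect_equal(m$A2, Tt * 15^2, tolerance = 1e-6)

  a <- beamline_element(thickness = 0.01, z_start = 0, T = 0.5)
  b <- beamline_element(thickness = 5, z_start = 5, T = 1e-4)
  mab <- accumulate_moments(list(a, b), 15)
  ma <- accumulate_moments(list(a), 15)
  mb <- accumulate_moments(list(b), 15)
  expect_equal(mab$A2, ma$A2 + mb$A2)
  expect_equal(mab$A1, ma$A1 + mb$A1)
  expect_equal(mab$A0, ma$A0 + mb$A0)

  expect_error(accumulate_moments(list(
    beamline_element(thickness = 1, z_start = 20, T = 1)), 15),
    "downstream")
})

test_that("moments respect the Cauchy-Schwarz inequality on random stacks", {
  set.seed(101)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    els <- lapply(seq_len(k), function(j)
      beamline_element(thickness = runif(1, 0.01, 5),
                       z_start = runif(1, -5, 8), T = runif(1, 1e-5, 0.5)))
    m <- accumulate_moments(els, 15)
    expect_lte(m$A1^2, m$A0 * m$A2 * (1 + 1e-12))
    expect_gte(m$A0, 0)
    expect_gte(m$A2, 0)
  }
})

test_that("incident fluence at z1 is a unit-normalized Gaussian", {
  m <- accumulate_moments(list(
    beamline_element(thickness = 0.01, z_start = 0, T = 3)), 15)
  p <- incident_fluence_z1(m, n = 20001, r_max = 12 * sqrt(m$A2))
  r <- p$r
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  integral <- trapz(r, 2 * pi * r * p$v)
  expect_equal(integral, 1, tolerance = 1e-6)
  # fraction inside the per-axis sigma sqrt(A2/2) is 1 - exp(-1/2)
  s_axis <- sqrt(m$A2 / 2)
  inside <- r <= s_axis
  frac <- trapz(r[inside], 2 * pi * r[inside] * p$v[inside])
  expect_equal(frac, 1 - exp(-0.5), tolerance = 2e-3)

  m0 <- accumulate_moments(list(), 15)
  expect_error(incident_fluence_z1(m0), "A2")
})

test_that("incident fluence width matches a Gaussian random-walk through the same stack", {
  set.seed(7)
  cfg <- toy_config(secondary_foil = list(mode = "none"),
                    xray = list(include = FALSE))
  walk <- mc_walk(cfg, n = 2e5)
  setup <- foilsim:::.build_transport(cfg)
  sigma_mc <- sqrt(mean(walk$r1^2))
  sigma_an <- sqrt(setup$moments_z1$A2)
  expect_equal(sigma_an, sigma_mc, tolerance = 0.01)
})

test_that("pencil kernel variance: drift-only limits and full-stack MC check", {
  geom <- beamline_geometry(3, 15, 85)
  L <- geom$z2 - geom$z1
  # uncorrelated beam (A1 = 0), no foil, subtract the air term
  m <- structure(list(A0 = 4e-3, A1 = 0, A2 = 2.5), class = "scattering_moments")
  v <- pencil_kernel_variance(0, NULL, geom, m, E_sec = 13)
  air_term <- reduced_gaussian_scattering_power("air", L, 13)$T * L^3 / 3
  expect_equal(v, 4e-3 * L^2 + air_term, tolerance = 1e-12)
  # zero upstream moments: air term only
  m0 <- structure(list(A0 = 0, A1 = 0, A2 = 0), class = "scattering_moments")
  expect_equal(pencil_kernel_variance(2, NULL, geom, m0, E_sec = 13),
               air_term, tolerance = 1e-12)
  # conditional term removes the correlated part
  mc_ <- structure(list(A0 = 4e-3, A1 = 0.08, A2 = 2.5),
                   class = "scattering_moments")
  v_cond <- pencil_kernel_variance(0, NULL, geom, mc_, E_sec = 13)
  v_unc <- pencil_kernel_variance(0, NULL, geom, mc_, E_sec = 13,
                                  kernel = "uncorrelated")
  expect_equal(v_unc - v_cond, 0.08^2 / 2.5 * L^2, tolerance = 1e-9)

  # full stack with a uniform-thickness secondary slab: the MC residual
  # variance of x2 given x1 equals half the (full-plane) kernel variance
  set.seed(11)
  cfg <- toy_config(secondary_foil = list(mode = "gaussian", t0 = 0.4,
                                          sigma = 50, n_segments = 1,
                                          r_max = 60))
  walk <- mc_walk(cfg, n = 3e5)
  fit <- stats::lm(x2 ~ x1, data = walk)
  resid_var <- stats::var(stats::residuals(fit))
  setup <- foilsim:::.build_transport(cfg)
  v_an <- pencil_kernel_variance(0, setup$foil, setup$geometry,
                                 setup$moments_z1,
                                 setup$energies$E_secondary_scatter)
  expect_equal(sqrt(v_an / 2), sqrt(resid_var), tolerance = 0.02)
})

test_that("no-secondary path is the analytic projected Gaussian", {
  cfg <- toy_config(secondary_foil = list(mode = "none"),
                    xray = list(include = FALSE))
  p <- electron_fluence_profile(cfg)
  r <- p$r[p$r >= 0 & p$v > 1e-300]
  v <- p$v[p$r >= 0 & p$v > 1e-300]
  fit <- stats::lm(log(v) ~ I(r^2))
  sigma_fit <- sqrt(-1 / unname(stats::coef(fit)[2]))
  expect_equal(sigma_fit, attr(p, "sigma_r"), tolerance = 1e-3)
  # symmetric by construction
  expect_identical(p$v, rev(p$v))
})

test_that("polar quadrature matches a dense Cartesian convolution within 0.5% of CAX", {
  cfg <- simulation_config()   # full default quadrature (100 x 100)
  cfg$calculation$n_profile <- 31
  p <- electron_fluence_profile(cfg)
  cax <- attr(p, "cax_absolute")
  r_out <- c(0, 3, 5, 8, 12, 16, 20)
  brute <- cartesian_convolution(cfg, r_out, n_grid = 641)
  mine <- profile_interp(p, r_out) * cax
  expect_lt(max(abs(mine - brute)) / cax, 0.005)
})

test_that("planar fluence is conserved through the convolution", {
  cfg <- toy_config()
  cfg$calculation$half_range <- 120   # capture essentially all the mass
  cfg$calculation$n_profile <- 241
  p <- electron_fluence_profile(cfg)
  cax <- attr(p, "cax_absolute")
  r <- p$r[p$r >= 0]
  v <- p$v[p$r >= 0] * cax
  integral <- sum(2 * pi * r * v) * diff(r)[1]
  expect_equal(integral, 1, tolerance = 0.01)
})

test_that("convolution agrees with the random-walk oracle off axis", {
  set.seed(23)
  # near-negligible window so that the mean pencil directions truly
  # emanate from the primary foil, as the projection rule assumes
  cfg <- toy_config(window = list(thickness = 1e-3),
                    geometry = list(d_window_primary = 0.5,
                                    d_primary_secondary = 15,
                                    d_secondary_iso = 85))
  walk <- mc_walk(cfg, n = 3e5)
  p <- electron_fluence_profile(cfg)
  cax <- attr(p, "cax_absolute")
  # cumulative fractions are statistically robust against binning noise
  r_probe <- c(5, 10, 20)
  frac_mc <- vapply(r_probe, function(r0) mean(walk$r2 <= r0), 0)
  r <- seq(0, 120, by = 0.1)
  cfg2 <- cfg
  cfg2$calculation$half_range <- 120
  cfg2$calculation$n_profile <- 1201
  p2 <- electron_fluence_profile(cfg2)
  v <- profile_interp(p2, r) * attr(p2, "cax_absolute")
  cum <- cumsum(2 * pi * r * v) * 0.1
  frac_an <- stats::approx(r, cum, xout = r_probe)$y
  expect_equal(frac_an, frac_mc, tolerance = 0.02)
})

test_that("sensitivity directions: primary widens the Gaussian, secondary shapes shoulders and horns", {
  base <- toy_config(secondary_foil = list(mode = "none"),
                     xray = list(include = FALSE))
  sig <- vapply(c(0.005, 0.008, 0.011), function(t) {
    cfg <- base
    cfg$primary_foil$thickness <- t
    attr(electron_fluence_profile(cfg), "sigma_r")
  }, 0)
  expect_true(all(diff(sig) > 0))

  shoulder <- function(cfg) {
    p <- electron_fluence_profile(cfg)
    profile_interp(p, 10)
  }
  cfgs_t0 <- lapply(c(0.3, 0.5, 0.7), function(t0)
    toy_config(secondary_foil = list(t0 = t0), xray = list(include = FALSE)))
  sh <- vapply(cfgs_t0, shoulder, 0)
  expect_true(all(diff(sh) > 0))

  horn <- function(cfg) {
    p <- electron_fluence_profile(cfg)
    max(p$v[abs(p$r) >= 5 & abs(p$r) <= 14.6])
  }
  cfgs_sg <- lapply(c(1.36, 1.44, 1.56), function(s)
    toy_config(secondary_foil = list(sigma = s), xray = list(include = FALSE)))
  hn <- vapply(cfgs_sg, horn, 0)
  expect_true(all(diff(hn) < 0))
})

test_that("fluence-to-dose conversion preserves the relative profile and checks Ed", {
  cfg <- toy_config(secondary_foil = list(mode = "none"))
  p <- electron_fluence_profile(cfg)
  d20 <- electron_dose_profile(p, Ep0 = 20, d = 2)
  expect_identical(d20$v, p$v)
  expect_equal(attr(d20, "Ed"), 16)
  d6 <- electron_dose_profile(p, Ep0 = 6, d = 1)
  expect_equal(attr(d6, "Ed"), 4)
  expect_gt(attr(d6, "Ke"), 0)
  expect_error(electron_dose_profile(p, Ep0 = 3, d = 2), "practical range")
})

test_that("secondary exit energy weighting: uniform slab and zero thickness limits", {
  m <- accumulate_moments(list(
    beamline_element(thickness = 0.01, z_start = 0, T = 2)), 15)
  flu <- incident_fluence_z1(m)
  slab <- segmented_foil(60, 0.4, "aluminum")
  expect_equal(secondary_exit_mean_energy(slab, flu, 12),
               mean_energy_after("aluminum", 0.4, 12), tolerance = 1e-12)
  thin <- segmented_foil(c(1, 2), c(1e-9, 1e-9), "aluminum")
  expect_equal(secondary_exit_mean_energy(thin, flu, 12), 12,
               tolerance = 1e-6)
  # matches a direct weighted sum over the same grid
  foil <- segment_gaussian_foil(gaussian_foil_spec("aluminum", 0.6, 1.44, 12))
  got <- secondary_exit_mean_energy(foil, flu, 12)
  r <- flu$r; v <- flu$v
  w <- v * r
  eout <- vapply(local_thickness(foil, r), function(t)
    if (t == 0) 12 else mean_energy_after("aluminum", t, 12), 0)
  expect_equal(got, sum(w * eout) / sum(w), tolerance = 1e-12)
  zero <- foil_profile(flu$r, rep(0, length(flu$r)), "absolute_per_electron")
  expect_error(secondary_exit_mean_energy(foil, zero, 12), "zero")
})
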