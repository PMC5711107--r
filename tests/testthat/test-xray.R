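# Bremsstrahlung budget, exponential-integral brackets and the
# central-axis calibration.

test_that("exponential integral matches an independent series/continued-fraction oracle", {
  xs <- c(1e-6, 1e-3, 0.1, 0.5, 1, 2, 5, 10, 30)
  expect_lt(max(abs(exp_integral_E1(xs) - e1_oracle(xs)) / e1_oracle(xs)),
            1e-10)
  expect_equal(exp_integral_E1(1), 0.2193839344, tolerance = 1e-9)
  expect_equal(exp_integral_E1(10), 4.15697e-6, tolerance = 1e-5)
  # small-x asymptote E1(x) ~ -gamma - ln x
  x <- 1e-12
  expect_lt(abs(exp_integral_E1(x) + log(x) + 0.5772156649), 1e-8)
  expect_error(exp_integral_E1(0), "x > 0")
  expect_error(exp_integral_E1(-1), "x > 0")
})

test_that("empirical incident moment follows 0.05 E^-1.6", {
  expect_identical(a00_empirical(1), 0.05)
  expect_equal(a00_empirical(10), 0.05 * 10^(-1.6), tolerance = 1e-12)
  expect_equal(a00_empirical(10), 1.2559e-3, tolerance = 1e-4)
  E <- seq(1, 25, by = 0.5)
  expect_true(all(diff(a00_empirical(E)) < 0))
  expect_error(a00_empirical(0))
})

make_budget <- function(cfg = NULL) {
  if (is.null(cfg)) cfg <- toy_config()
  setup <- foilsim:::.build_transport(cfg)
  list(setup = setup,
       budget = build_xray_budget(cfg$window, cfg$primary_foil, setup$foil,
                                  setup$energies, setup$fluence_z1))
}

test_that("budget chains entrance moments per the accumulation rule", {
  mb <- make_budget()
  b <- mb$budget
  A00 <- attr(b, "A00")
  expect_equal(A00, a00_empirical(mb$setup$energies$E_incident))
  expect_equal(b$A0_entry[1], A00)
  expect_equal(b$A0_entry[2], b$A0_entry[1] + b$T[1] * b$t[1])
  expect_equal(b$A0_entry[3], b$A0_entry[2] + b$T[2] * b$t[2])
  expect_true(all(b$dE_rad >= 0) && all(b$T >= 0) && all(b$t >= 0))
  # per-element radiative losses recompute from stopping power x thickness
  en <- mb$setup$energies
  win <- get_material("nickel")
  expect_equal(b$dE_rad[1],
               radiative_mass_stopping_power(win, en$E_incident) *
                 win$density * b$t[1])
})

test_that("fluence-weighted mean secondary thickness lies between edge and axis values", {
  mb <- make_budget()
  foil <- mb$setup$foil
  t_sec <- mb$budget$t[3]
  expect_gt(t_sec, 0)
  expect_lt(t_sec, local_thickness(foil, 0))
  cfg <- toy_config(calculation = list(t_secondary = "cax"))
  setup <- foilsim:::.build_transport(cfg)
  b_cax <- build_xray_budget(cfg$window, cfg$primary_foil, setup$foil,
                             setup$energies, setup$fluence_z1, "cax")
  expect_equal(b_cax$t[3], local_thickness(foil, 0))
})

test_that("off-axis X-ray relative dose: unity on axis, series limit, monotone decay", {
  mb <- make_budget()
  b <- mb$budget
  expect_identical(offaxis_xray_relative(b, 102, 0), 1)
  # numeric E1 difference approaches the logarithmic r -> 0 limit
  rel_eps <- offaxis_xray_relative(b, 102, 1e-5)
  expect_lt(abs(rel_eps - 1), 1e-6)
  r <- seq(0, 20, by = 0.5)
  rel <- offaxis_xray_relative(b, 102, r)
  expect_true(all(diff(rel) <= 0))
  expect_true(all(rel > 0 & rel <= 1))
  # every element bracket obeys the log limit individually
  for (i in 1:3) {
    Tt <- b$T[i] * b$t[i]
    A0 <- b$A0_entry[i]
    th2 <- (1e-5 / 102)^2
    num <- exp_integral_E1(th2 / (A0 + Tt)) - exp_integral_E1(th2 / A0)
    expect_equal(num, log1p(Tt / A0), tolerance = 1e-6)
  }
})

test_that("zero-thickness secondary contributes nothing to the brackets", {
  cfg <- toy_config(secondary_foil = list(mode = "none"))
  setup <- foilsim:::.build_transport(cfg)
  b2 <- build_xray_budget(cfg$window, cfg$primary_foil, NULL,
                          setup$energies, setup$fluence_z1)
  expect_equal(nrow(b2), 2)
  s2 <- foilsim:::.budget_bracket_sum(b2, 0)
  # compare against a 3-element budget whose secondary has T t -> 0
  b3 <- b2
  b3[3, ] <- list("secondary", 0, 0, 0, b2$A0_entry[2] +
                    b2$T[2] * b2$t[2])
  class(b3) <- class(b2)
  expect_equal(foilsim:::.budget_bracket_sum(b3, 0), s2)
})

test_that("toy budget bracket sum matches hand arithmetic", {
  b <- data.frame(element = c("window", "primary", "secondary"),
                  dE_rad = c(0.05, 0.3, 0.4),
                  T = c(1, 2, 4), t = c(0.01, 0.01, 0.02),
                  A0_entry = c(0.01, 0.02, 0.04))
  attr(b, "A00") <- 0.01
  class(b) <- c("xray_budget", "data.frame")
  hand <- 0.05 / 0.01 * log(1 + 0.01 / 0.01) +
    0.3 / 0.02 * log(1 + 0.02 / 0.02) +
    0.4 / 0.08 * log(1 + 0.08 / 0.04)
  expect_equal(foilsim:::.budget_bracket_sum(b, 0), hand, tolerance = 1e-12)
  # single element with T t = A0 gives dE/(T t) ln 2
  b1 <- b[1, ]; class(b1) <- class(b)
  expect_equal(foilsim:::.budget_bracket_sum(b1, 0), 5 * log(2))
})

test_that("practical range follows the 2 MeV/cm rule", {
  expect_equal(practical_range(20), 10)
  expect_equal(practical_range(7), 3.5)
  expect_equal(practical_range(0.1), 0.05)
  expect_error(practical_range(0))
})

test_that("X statistic scales linearly with radiative losses and inversely with fluence", {
  mb <- make_budget()
  b <- mb$budget
  X <- x_statistic(b, 3e-4, Rp = 6, SAD = 100)
  b2 <- b; b2$dE_rad <- 2 * b$dE_rad
  class(b2) <- class(b)
  expect_equal(x_statistic(b2, 3e-4, 6, 100), 2 * X, tolerance = 1e-12)
  expect_equal(x_statistic(b, 1.5e-4, 6, 100), 2 * X, tolerance = 1e-12)
  expect_error(x_statistic(b, 0, 6, 100), "fluence")
  # hand check on a single-element budget with T t = A0
  b1 <- data.frame(element = "window", dE_rad = 0.2, T = 1, t = 0.01,
                   A0_entry = 0.01)
  class(b1) <- c("xray_budget", "data.frame")
  expect_equal(x_statistic(b1, 1e-3, Rp = 8, SAD = 100),
               (0.2 / 0.01) * log(2) / (110^2 * 1e-3), tolerance = 1e-12)
})

test_that("central-axis calibration: origin, asymptote, clamping", {
  cal <- xray_calibration()
  expect_identical(cax_xray_percent(0, cal), 0)
  expect_equal(cax_xray_percent(100, cal),
               -0.035 * 100 + 15.77 * (1 - exp(-1.6)), tolerance = 1e-12)
  expect_equal(cax_xray_percent(100, cal), 9.0855, tolerance = 1e-4)
  # far beyond the fitted range the linear term dominates: clamp + warn
  expect_warning(v <- cax_xray_percent(5000, cal), "clamped")
  expect_identical(v, 0)
  # the saturation level is approached as X grows (before the linear
  # term drives the fit negative)
  X <- 400
  expect_equal(cax_xray_percent(X, cal) - cal$a * X, cal$b,
               tolerance = 5e-3)
})

test_that("depth rescaling is pure inverse square", {
  expect_equal(cax_xray_percent_at_depth(5, Rp = 10, d = 12, SAD = 100), 5)
  expect_equal(cax_xray_percent_at_depth(1, Rp = 10, d = 0, SAD = 100),
               1.2544, tolerance = 1e-12)
  ds <- seq(0, 10, by = 1)
  fac <- vapply(ds, function(d)
    cax_xray_percent_at_depth(1, 10, d, 100), 0)
  expect_true(all(diff(fac) < 0))
})

test_that("off-axis percent profile is the product of its factors", {
  mb <- make_budget()
  cfg <- toy_config()
  geom <- mb$setup$geometry
  Ep0 <- mb$setup$energies$Ep0
  cax_flu <- 3e-4
  r <- seq(-20, 20, by = 2)
  p <- offaxis_xray_percent_profile(mb$budget, xray_calibration(), geom,
                                    Ep0, cax_flu, r)
  Rp <- practical_range(Ep0)
  X <- x_statistic(mb$budget, cax_flu, Rp, geom$SAD)
  pct_d <- cax_xray_percent_at_depth(cax_xray_percent(X), Rp,
                                     geom$calc_depth, geom$SAD)
  rel <- offaxis_xray_relative(mb$budget, geom$SAD + geom$calc_depth, r)
  expect_equal(p$v, rel * pct_d, tolerance = 1e-12)
  expect_equal(profile_interp(p, 0), pct_d, tolerance = 1e-12)
  # scaling b scales the profile at fixed shape
  p2 <- offaxis_xray_percent_profile(mb$budget,
                                     xray_calibration(b = 2 * 15.77),
                                     geom, Ep0, cax_flu, r)
  ratio <- p2$v / p$v
  expect_lt(diff(range(ratio)), 1e-9)
})
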