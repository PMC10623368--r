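test_that("empty-cavity collapse reproduces the 0.915 Rayleigh coefficient", {
  expect_equal(rayleigh_collapse_coefficient(1e-3), 0.915, tolerance = 5e-4)
})

test_that("the collapse coefficient is invariant over two decades of scale", {
  w <- ambient_water()
  c1 <- rayleigh_collapse_coefficient(0.1e-3)
  c2 <- rayleigh_collapse_coefficient(10e-3)
  w2 <- w; w2$p_stat <- w$p_stat * 50
  c3 <- rayleigh_collapse_coefficient(1e-3, fluid = w2)
  expect_equal(c1, c2, tolerance = 1e-4)
  expect_equal(c1, c3, tolerance = 1e-4)
})

test_that("fixed-step RK4 agrees with the adaptive integrator", {
  cA <- rayleigh_collapse_coefficient(1e-3)
  cR <- rayleigh_collapse_coefficient(1e-3, method = "rk4")
  expect_equal(cR, cA, tolerance = 1e-3)
})

test_that("a pressurized bubble oscillates instead of collapsing to zero", {
  w <- ambient_water()
  # gas law keeping p R^3 constant, overpressured start
  p_in <- function(R, t) 2 * w$p_stat * (1e-3 / R)^3
  sol <- integrate_rayleigh(5e-4, p_inside = p_in, t_end = 3e-4)
  expect_false(sol$collapsed)
  expect_gt(min(sol$R), 0)
})

test_that("saturation pressure matches steam-table anchors within 2%", {
  # standard saturation anchors (Pa): 100 C, 150 C, 200 C, 260 C, 350 C
  anchors <- data.frame(T = c(373.15, 423.15, 473.15, 533.15, 623.15),
                        p = c(101325, 4.758e5, 1.5549e6, 4.6923e6, 16.529e6))
  expect_equal(saturation_pressure(anchors$T), anchors$p, tolerance = 0.02)
  expect_error(saturation_pressure(200), "range")
})

test_that("initial bubble pressure models behave as specified", {
  w <- ambient_water()
  # saturation model at ambient temperature returns the ambient vapor pressure
  expect_equal(initial_bubble_pressure(w$T0, "saturation"), w$p_v, tolerance = 0.01)
  # isochoric flash pressure spans the 0.15-0.22 GPa band over the
  # homogeneous-nucleation window
  Ts <- seq(373.15, 533.15, by = 20)
  p <- initial_bubble_pressure(Ts, "isochoric")
  expect_true(all(p >= 0.15e9 & p <= 0.225e9))
  expect_error(initial_bubble_pressure(700), "window")
})

test_that("latent heat requirement is bilinear and matches the printed band", {
  expect_equal(latent_heat_required(0), 0)
  # 1e-10 m^3 of saturated vapor at 373 K: 0.135 mJ, inside 0.12-0.26 mJ
  E <- latent_heat_required(1.0e-10, 373.15, 0.598, 2.257e6)
  expect_equal(E, 1.35e-4, tolerance = 0.01)
  expect_gt(E, 0.12e-3); expect_lt(E, 0.26e-3)
  expect_equal(latent_heat_required(2e-10, 373.15, 0.598, 2.257e6), 2 * E)
  expect_equal(latent_heat_required(1e-10, 373.15, 1.196, 2.257e6), 2 * E,
               tolerance = 1e-9)
})

test_that("adiabatic nucleation matches the closed-form flat-top limit", {
  p <- make_power_profile(0.2, 70e-6, "flat")
  opt <- get_material("water", "optical"); th <- get_material("water", "thermal")
  res <- absorbed_energy_to_nucleation(p, T_vap = 373.15, conduction = "off")
  I0 <- max(p$power) / (pi * (p$fiber_core_diameter / 2)^2)
  t_cf <- th$rho * th$cp * (373.15 - 293.15) / (opt$mu_a_si * I0)
  expect_equal(res$t_nucleation, t_cf, tolerance = 0.02)
  expect_true(res$reached)
})

test_that("degenerate and failing nucleation cases are explicit", {
  p <- make_power_profile(0.2, 70e-6)
  r0 <- absorbed_energy_to_nucleation(p, T_vap = 293.15)
  expect_equal(r0$t_nucleation, 0)
  expect_equal(r0$E_absorbed, 0)
  weak <- make_power_profile(1e-4, 70e-6)  # 0.1 mJ cannot superheat the face
  rf <- absorbed_energy_to_nucleation(weak, T_vap = 373.15)
  expect_false(rf$reached)
  expect_true(is.na(rf$t_nucleation))
})

test_that("nucleation energy is nondecreasing in the vaporization temperature", {
  p <- make_power_profile(0.2, 70e-6)
  Es <- vapply(c(373.15, 423.15, 473.15, 533.15), function(Tv)
    absorbed_energy_to_nucleation(p, T_vap = Tv)$E_absorbed, numeric(1))
  expect_true(all(diff(Es) > 0))
})

test_that("conduction-limited nucleation is later and costlier than adiabatic", {
  p <- make_power_profile(0.2, 70e-6)
  off <- absorbed_energy_to_nucleation(p, conduction = "off")
  on <- absorbed_energy_to_nucleation(p, conduction = "on")
  expect_gte(on$t_nucleation, off$t_nucleation)
  expect_gte(on$E_absorbed, off$E_absorbed)
  # absorbed energy at nucleation sits in the tens-of-mJ scale reported for
  # dusting pulses (profile-dependent plausibility band)
  expect_gt(on$E_absorbed, 5e-3); expect_lt(on$E_absorbed, 60e-3)
  expect_gt(on$nucleus_volume, 0)
})
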