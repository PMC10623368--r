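test_that("zero source leaves a uniform field unchanged", {
  fld <- thermal_field(n = list(r = 16L, z = 16L))
  out <- step_heat(fld, 0, dt = 1e-5)
  expect_equal(out$temperature, fld$temperature, tolerance = 1e-12)
})

test_that("an instantaneous point release matches the 3D heat kernel", {
  m <- get_material("water", "thermal")
  fld <- thermal_field(medium = m, extent = list(r = 0.5e-3, z = 1.0e-3),
                       n = list(r = 96L, z = 192L), T0 = 293.15)
  g <- fld$grid
  Q <- 1e-4; j0 <- 96L
  fld$temperature[1, j0] <- fld$temperature[1, j0] +
    Q / (m$rho * m$cp * 2 * pi * g$r[1] * g$dr * g$dz)
  alpha <- m$k_cond / (m$rho * m$cp)
  dt <- 2.5e-5
  st <- lithocav:::heat_stepper(fld, dt)
  for (i in 1:100) fld <- step_heat(fld, 0, dt, stepper = st)
  tt <- 100 * dt
  kern <- function(r) Q / (m$rho * m$cp * (4 * pi * alpha * tt)^1.5) *
    exp(-r^2 / (4 * alpha * tt))
  for (k in c(4, 6, 8, 10, 12)) {
    expect_equal(fld$temperature[k, j0] - 293.15, kern(g$r[k]), tolerance = 0.03)
  }
})

test_that("an insulated domain conserves injected enthalpy to 0.1%", {
  fld <- thermal_field(n = list(r = 24L, z = 24L))
  g <- fld$grid
  set.seed(3)
  injected <- 0
  st <- lithocav:::heat_stepper(fld, 1e-4)
  for (k in 1:5) {
    src <- matrix(runif(g$nr * g$nz, 0, 1e12), g$nr, g$nz)
    fld <- step_heat(fld, src, 1e-4, stepper = st)
    vol <- 2 * pi * g$r * g$dr * g$dz
    injected <- injected + sum(src * vol) * 1e-4
  }
  for (k in 1:10) fld <- step_heat(fld, 0, 1e-4, stepper = st)
  expect_equal(field_enthalpy(fld), injected, tolerance = 1e-3)
})

test_that("ablation criterion matches a brute-force scan and removes volume", {
  fld <- thermal_field(n = list(r = 12L, z = 12L))
  set.seed(7)
  fld$temperature <- matrix(runif(144, 293, 900), 12, 12)
  fld$deposited <- matrix(runif(144, 0, 6e9), 12, 12)
  TR <- 3e9
  manual <- fld$temperature >= fld$medium$melt_T & fld$deposited > TR
  g <- fld$grid
  manual_vol <- sum((2 * pi * g$r * g$dr * g$dz)[row(manual)[manual]])
  ab <- apply_ablation(fld, TR)
  expect_equal(ab$removed_cells, sum(manual))
  expect_equal(ab$removed_volume, manual_vol)
  # below-threshold field removes nothing, and ablated cells never revert
  ab2 <- apply_ablation(ab$field, TR)
  expect_equal(ab2$removed_volume, 0)
  expect_true(all(ab$field$ablated[manual]))
})

test_that("single cell forced above both thresholds is removed exactly", {
  fld <- thermal_field(n = list(r = 10L, z = 10L))
  fld$temperature[3, 1] <- 2000
  fld$deposited[3, 1] <- 1e10
  g <- fld$grid
  ab <- apply_ablation(fld, 1e9)
  expect_equal(ab$removed_cells, 1L)
  expect_equal(ab$removed_volume, 2 * pi * g$r[3] * g$dr * g$dz)
})

test_that("surface irradiance follows the cone-divergence arithmetic", {
  p <- make_power_profile(0.2, 70e-6, "flat")
  irr0 <- surface_irradiance(p, SD = 0)
  # 2857 W over the 365 um core: ~2.73e4 W/mm^2
  expect_equal(irr0$irradiance / 1e6, 2.73e4, tolerance = 0.01)
  sds <- seq(0, 2.5e-3, by = 0.5e-3)
  irr <- vapply(sds, function(s) surface_irradiance(p, s)$irradiance, numeric(1))
  expect_true(all(diff(irr) < 0))  # strictly decreasing with standoff
  # by SD = 2.5 mm the PRF-averaged irradiance is near the reported
  # ablation-threshold scale (W/mm^2, order of magnitude)
  irr_prf <- surface_irradiance(p, 2.5e-3, prf_averaged = TRUE, prf = 20)
  expect_lt(irr_prf$irradiance / 1e6, 50)
  expect_gt(irr_prf$irradiance / 1e6, 0.5)
})

test_that("multi-pulse crater growth is monotone and zero without absorption", {
  ch0 <- run_multi_pulse(0.5e-3, absorbed_fraction = 0, n_pulses = 3L,
                         field = thermal_field(n = list(r = 24L, z = 24L)))
  expect_true(all(ch0$volume_mm3 == 0))
  ch <- as.data.frame(run_multi_pulse(0.5e-3, n_pulses = 60L))
  expect_true(all(diff(ch$volume_mm3) >= 0))
  expect_true(all(diff(ch$max_depth_mm) >= 0))
  expect_gt(ch$volume_mm3[60], 0)
})
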