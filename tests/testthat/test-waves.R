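# Wave-solver checks use coarse grids sized so each simulation stays in the
# seconds range; physical tolerances follow from those resolutions.

test_that("Rayleigh speed solves the characteristic equation and matches Viktorov", {
  qz <- get_material("quartz", "elastic")
  cR <- rayleigh_wave_speed(qz)
  nu <- (qz$c_L^2 - 2 * qz$c_T^2) / (2 * (qz$c_L^2 - qz$c_T^2))
  viktorov <- qz$c_T * (0.87 + 1.12 * nu) / (1 + nu)
  expect_equal(cR, viktorov, tolerance = 0.005)
  expect_lt(cR, qz$c_T)
  # residual of the characteristic equation at the root
  xi <- cR / qz$c_T; kap <- qz$c_L / qz$c_T
  expect_equal((2 - xi^2)^2,
               4 * sqrt(1 - xi^2) * sqrt(1 - xi^2 / kap^2), tolerance = 1e-8)
})

test_that("calibrated free-field pressure follows the 1/r spherical law", {
  src <- build_source(30e5, pulse_width = 0.5e-6, h_c = 50e-6, h = 10e-6)
  res <- simulate_waves(src, solid = NULL, r_extent = 2.4e-3, z_fluid = 2.4e-3,
                        duration = 1.3e-6,
                        stations_r = c(0.5e-3, 1.0e-3, 1.5e-3),
                        energy_every = 50L)
  p <- -(res$raw$srr + res$raw$stt + res$raw$szz) / 3
  pk <- apply(p, 2, function(v) max(abs(v)))
  pr <- pk * res$stations_r
  # peak at 1 mm equals the specified source strength (30 bar referenced there)
  expect_equal(pk[2], 30e5, tolerance = 0.03)
  # 1/r: peak*r constant across a factor 3 in radius
  expect_lt(max(pr) / min(pr) - 1, 0.05)
  # discrete energy decays after source switch-off (absorbing boundaries)
  e <- res$energy
  expect_lt(e[length(e)], max(e))
})

test_that("radiated spherical-wave energy is independent of the capture radius", {
  w <- ambient_water()
  src <- build_source(30e5, pulse_width = 0.4e-6, h_c = 50e-6, h = 10e-6)
  res <- simulate_waves(src, solid = NULL, r_extent = 2.6e-3, z_fluid = 2.6e-3,
                        duration = 2.1e-6, stations_r = 0.5e-3,
                        gauges = data.frame(r = c(0.7e-3, 1.4e-3), height = c(0, 0)))
  Es <- vapply(1:2, function(k)
    4 * pi * res$gauges$r[k]^2 / (w$rho * w$c) *
      sum(res$gauge_pressure[, k]^2) * res$dt, numeric(1))
  expect_equal(Es[2] / Es[1], 1, tolerance = 0.03)
})

test_that("normal-incidence reflection matches the impedance closed form", {
  w <- ambient_water(); qz <- get_material("quartz", "elastic")
  src <- build_source(30e5, pulse_width = 0.3e-6, h_c = 1.2e-3, h = 8e-6)
  res <- simulate_waves(src, solid = qz, r_extent = 2.0e-3, z_fluid = 1.8e-3,
                        z_solid = 0.6e-3, duration = 1.6e-6, stations_r = 0.1e-3,
                        gauges = data.frame(r = 4e-6, height = 0.5e-3))
  p <- res$gauge_pressure[, 1]; t <- res$times
  d1 <- 0.7e-3; d2 <- 1.7e-3  # direct and image-source path lengths
  p_inc <- max(abs(p[t < (d1 / w$c + 2.2 * src$pulse_width)]))
  p_ref <- max(abs(p[t > d2 / w$c - 0.1e-6]))
  R_meas <- (p_ref * d2) / (p_inc * d1)
  Z1 <- w$rho * w$c; Z2 <- qz$rho * qz$c_L
  R_cf <- (Z2 - Z1) / (Z2 + Z1)
  expect_equal(R_cf, 0.798, tolerance = 0.001)   # water -> fused quartz
  expect_equal(R_meas, R_cf, tolerance = 0.03)
})

test_that("a near-rigid solid doubles the boundary pressure", {
  bego <- get_material("begostone", "elastic")
  rigid <- bego; rigid$rho <- 1e6; rigid$c_L <- 6000; rigid$c_T <- 3500
  src <- build_source(10e5, pulse_width = 0.3e-6, h_c = 0.5e-3, h = 8e-6)
  resR <- simulate_waves(src, solid = rigid, r_extent = 1.4e-3, z_fluid = 1.0e-3,
                         z_solid = 0.3e-3, duration = 0.9e-6, stations_r = 0.5e-3,
                         gauges = data.frame(r = 4e-6, height = 2e-5))
  resF <- simulate_waves(src, solid = NULL, r_extent = 1.4e-3, z_fluid = 2.0e-3,
                         duration = 0.9e-6, stations_r = 0.5e-3,
                         gauges = data.frame(r = 4e-6, height = 2e-5))
  ratio <- max(resR$gauge_pressure) / max(resF$gauge_pressure)
  expect_equal(ratio, 2, tolerance = 0.06)
})

test_that("the direct wavefront travels at the fluid sound speed", {
  w <- ambient_water()
  src <- build_source(30e5, pulse_width = 0.3e-6, h_c = 50e-6, h = 10e-6)
  res <- simulate_waves(src, solid = NULL, r_extent = 2.2e-3, z_fluid = 2.2e-3,
                        duration = 1.2e-6,
                        stations_r = c(0.6e-3, 1.5e-3))
  p <- -(res$raw$srr + res$raw$stt + res$raw$szz) / 3
  arr <- vapply(1:2, function(k) {
    thr <- 0.2 * max(abs(p[, k]))
    res$times[which(abs(p[, k]) >= thr)[1]]
  }, numeric(1))
  c_meas <- diff(res$stations_r) / diff(arr)
  expect_equal(c_meas, w$c, tolerance = 0.02)
})

test_that("principal stresses match the eigen-decomposition oracle", {
  expect_equal(principal_stresses(0, 1e6, 0, 0),
               list(sigma1 = 1e6, sigma3 = 0))          # uniaxial tension
  ps <- principal_stresses(0, 0, 0, 5e5)                # pure shear
  expect_equal(ps$sigma1, 5e5); expect_equal(ps$sigma3, -5e5)
  set.seed(11)
  for (i in 1:100) {
    s <- rnorm(4, sd = 1e6)  # srr, szz, stt, srz
    M <- matrix(c(s[1], 0, s[4], 0, s[3], 0, s[4], 0, s[2]), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    ps <- principal_stresses(s[1], s[2], s[3], s[4])
    expect_equal(ps$sigma1, max(ev), tolerance = 1e-9)
    expect_equal(ps$sigma3, min(ev), tolerance = 1e-9)
  }
})

test_that("peak boundary tension is grid-converged under 2x refinement", {
  bego <- get_material("begostone", "elastic")
  pk <- vapply(c(6e-6, 3e-6), function(h) {
    src <- build_source(30e5, h_c = 48e-6, h = h)
    res <- simulate_waves(src, solid = bego, r_extent = 1.2e-3,
                          z_fluid = 0.5e-3, z_solid = 0.45e-3,
                          duration = 0.9e-6,
                          stations_r = seq(0.2e-3, 0.7e-3, by = 0.1e-3))
    max(apply(res$sigma1, 2, max))
  }, numeric(1))
  expect_equal(pk[2] / pk[1], 1, tolerance = 0.05)
})

test_that("unresolvable source pulses are rejected", {
  expect_error(build_source(30e5, pulse_width = 1e-8, h = 10e-6), "unresolvable")
})
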