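test_that("bubble energetics evaluate the printed formulas", {
  rt <- make_radius_time(1e-3, 90e-6, 1.2, 0.3)
  be <- bubble_energetics(rt, SD = 0.5e-3)
  # EB = (4pi/3) (p_stat - p_v) Re_max^3 = 4.15e-4 J for Re_max = 1 mm
  expect_equal(be$EB, 4 * pi / 3 * 98986 * 1e-9, tolerance = 1e-3)
  expect_equal(be$EB, 4.15e-4, tolerance = 0.01)
  expect_equal(be$gamma, 0.5, tolerance = 1e-6)
  # gamma example: SD = 0.5 mm, Re_max = 1.6 mm
  rt2 <- make_radius_time(1.6e-3, 140e-6, 1.2, 0.3)
  expect_equal(bubble_energetics(rt2, 0.5e-3)$gamma, 0.3125, tolerance = 1e-3)
})

test_that("significant-peak selection applies the strict 30% rule", {
  tr <- make_hydrophone_trace(
    data.frame(time = c(50, 80, 110, 140, 170) * 1e-6,
               p_1mm = c(10, 4, 3.5, 2, 1) * 1e5),
    sensor_distance = 10e-3, noise_rms = 0, seed = 1)
  pk <- detect_significant_peaks(tr)
  expect_equal(nrow(pk), 5L)
  expect_equal(sum(pk$significant), 3L)  # 10, 4, 3.5 > 3 = 0.3 * 10
  # exactly 30% of the maximum is NOT significant (strict inequality)
  tr2 <- make_hydrophone_trace(data.frame(time = c(50e-6, 120e-6),
                                          p_1mm = c(10e5, 3e5)),
                               sensor_distance = 10e-3, noise_rms = 0, seed = 1)
  pk2 <- detect_significant_peaks(tr2)
  expect_identical(pk2$significant, c(TRUE, FALSE))
  # a single peak is its own maximum and therefore significant
  tr3 <- make_hydrophone_trace(data.frame(time = 50e-6, p_1mm = 1e5),
                               sensor_distance = 10e-3, noise_rms = 0, seed = 1)
  expect_identical(detect_significant_peaks(tr3)$significant, TRUE)
})

test_that("an all-zero trace yields an empty peak set", {
  tr <- list(times = seq(0, 1e-4, 1e-7), pressure = numeric(1001),
             sensor_distance = 10e-3, noise_rms = 0)
  expect_equal(nrow(detect_significant_peaks(tr)), 0L)
})

test_that("1/r scaling to 1 mm and its round trip", {
  expect_equal(scale_to_1mm(5e5, 1e-3), 5e5)
  expect_equal(scale_to_1mm(3e5, 10e-3), 30e5)     # 3 bar at 10 mm -> 30 bar
  p <- 7.3e5
  expect_equal(scale_to_1mm(p, 10e-3) * (1e-3 / 10e-3), p)
  expect_error(scale_to_1mm(1e5, 0), "positive")
})

test_that("pressure impulse integrates rectangles and refines consistently", {
  tr <- list(times = seq(0, 10e-6, by = 1e-8),
             pressure = rep(0, 1001), sensor_distance = 10e-3)
  tr$pressure[tr$times >= 2e-6 & tr$times <= 4e-6] <- 5e5
  expect_equal(pressure_impulse(tr, c(1e-6, 5e-6)), 1.0, tolerance = 0.01)
  # refined-grid quadrature of a smooth burst agrees to 0.1%
  f <- function(t) 1e5 * exp(-((t - 5e-6) / 1e-6)^2)
  t1 <- seq(0, 1e-5, by = 2e-8); t2 <- seq(0, 1e-5, by = 2e-9)
  pi1 <- pressure_impulse(list(times = t1, pressure = f(t1)), c(0, 1e-5))
  pi2 <- pressure_impulse(list(times = t2, pressure = f(t2)), c(0, 1e-5))
  expect_equal(pi1, pi2, tolerance = 1e-3)
  expect_warning(out <- pressure_impulse(list(times = t1, pressure = f(t1)),
                                         c(5e-6, 5e-6 + 1e-9)), "empty")
  expect_equal(out, 0)
})

test_that("acoustic emission energy matches the spherical-wave closed form", {
  tr <- list(times = seq(0, 5e-6, by = 1e-9), pressure = numeric(5001),
             sensor_distance = 10e-3)
  tr$pressure[tr$times >= 1e-6 & tr$times <= 2e-6] <- 1e5
  # 4 pi r^2 p^2 tau / (rho c) = 8.5e-6 J
  expect_equal(acoustic_emission_energy(tr), 8.5e-6, tolerance = 0.01)
  # distance independence when amplitudes follow 1/r
  tr2 <- tr; tr2$sensor_distance <- 20e-3; tr2$pressure <- tr$pressure / 2
  expect_equal(acoustic_emission_energy(tr2), acoustic_emission_energy(tr),
               tolerance = 1e-9)
  tr0 <- tr; tr0$pressure <- numeric(5001)
  expect_equal(acoustic_emission_energy(tr0), 0)
})

test_that("two-burst emission metrics recover the generator amplitude ratio", {
  tr <- make_hydrophone_trace(data.frame(time = c(100e-6, 300e-6),
                                         p_1mm = c(30e5, 10e5)),
                              sensor_distance = 10e-3, noise_rms = 0, seed = 1)
  em <- emission_metrics(tr, t_split = 200e-6)
  expect_equal(em$p1, 30e5, tolerance = 1e-6)
  expect_equal(em$p2, 10e5, tolerance = 1e-6)
  expect_equal(em$p1_over_p2, 3, tolerance = 1e-6)
  expect_gt(em$Es1, em$Es2)
})

test_that("torus volume matches the revolution integral and its scaling", {
  expect_equal(torus_volume(1e-3, 0), 0)
  rc <- 0.56e-3; rt <- 0.1e-3
  # numeric solid-of-revolution oracle for a circular cross-section torus
  zs <- seq(-rt, rt, length.out = 4001)
  half_w <- sqrt(rt^2 - zs^2)
  V_num <- lithocav:::trapz(zs, pi * ((rc + half_w)^2 - (rc - half_w)^2))
  expect_equal(torus_volume(rc, rt), V_num, tolerance = 5e-3)
  expect_equal(torus_volume(rc, rt), 2 * pi^2 * rc * rt^2, tolerance = 1e-12)
  # halving the cross-section radius at fixed centerline gives ratio 4
  ratio <- compression_ratio(list(r_c = rc, r_torus = rt),
                             list(r_c = rc, r_torus = rt / 2))
  expect_equal(ratio, 4)
  expect_error(torus_volume(1e-4, 2e-4), "exceed")
})

test_that("collision speed is the commutative sum of wall speeds", {
  expect_equal(collision_speed(0, 12), 12)
  expect_equal(collision_speed(29, 39), 68)
  expect_equal(collision_speed(39, 29), collision_speed(29, 39))
})

test_that("shock Mach number from the measured speeds", {
  expect_equal(mach_number(1820), 1.23, tolerance = 0.002)
})
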