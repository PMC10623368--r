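test_that("Beer-Lambert transmission matches the closed form and its laws", {
  expect_equal(beer_lambert_transmission(0, 12345), 1)
  expect_equal(beer_lambert_transmission(0.5e-3, 2420), exp(-1.21), tolerance = 1e-12)
  # multiplicativity over random path splits
  set.seed(1)
  for (i in 1:25) {
    a <- runif(1, 0, 2e-3); b <- runif(1, 0, 2e-3); mu <- runif(1, 100, 5000)
    expect_equal(beer_lambert_transmission(a + b, mu),
                 beer_lambert_transmission(a, mu) * beer_lambert_transmission(b, mu),
                 tolerance = 1e-12)
  }
  expect_error(beer_lambert_transmission(-1, 2420), "non-negative")
})

test_that("collimated transport through homogeneous water matches Beer-Lambert", {
  m <- make_media_map(0.5e-3)
  dm <- trace_segment(1, m, n_photons = 2e4, seed = 7, collimated = TRUE)
  # exact for straight paths (continuous attenuation is analytic per step)
  expect_equal(dm$transmitted, exp(-2420 * 0.5e-3), tolerance = 1e-6)
  expect_equal(dm$absorbed_total, 1 - exp(-2420 * 0.5e-3), tolerance = 1e-6)
})

test_that("energy bookkeeping closes to 1e-6 in all media", {
  g <- make_bubble_geometry_sequence(0.5e-3, 1.5e-3, n_seg = 6L, n_contact = 2L)
  for (s in c(1L, 4L, 6L)) {
    media <- make_media_map(0.5e-3, vapor_mask = g$masks[[s + 1L]])
    dm <- trace_segment(0.01, media, n_photons = 5e3, seed = s)
    expect_equal(dm$absorbed_total + dm$transmitted + dm$escaped, dm$launched,
                 tolerance = 1e-6)
  }
})

test_that("zero-absorption media deposit nothing and conserve energy", {
  opt0 <- list(water = within(get_material("water", "optical"),
                              {mu_a <- 0; mu_a_si <- 0}),
               vapor = within(get_material("vapor", "optical"),
                              {mu_a <- 0; mu_a_si <- 0}))
  m <- make_media_map(0.5e-3, optics = opt0)
  dm <- trace_segment(1, m, n_photons = 5e3, seed = 3)
  expect_equal(dm$absorbed_total, 0)
  expect_equal(dm$transmitted + dm$escaped, dm$launched, tolerance = 1e-9)
})

test_that("full vapor channel transmits above the fragmenting bound", {
  vc <- vapor_channel_transmission(0.5e-3, n_photons = 2e4, seed = 11)
  expect_gte(vc$transmission_percent, 80)
})

test_that("Monte Carlo error follows the sqrt(N) law over replicates", {
  g <- make_bubble_geometry_sequence(0.5e-3, 1.5e-3, n_seg = 6L, n_contact = 2L)
  media <- make_media_map(0.5e-3, vapor_mask = g$masks[[4L]])
  frac <- function(n, seeds) vapply(seeds, function(s)
    trace_segment(1, media, n_photons = n, seed = s)$transmitted, numeric(1))
  v1 <- stats::var(frac(1000, 1:12))
  v4 <- stats::var(frac(4000, 101:112))
  # quadrupling N divides the variance by ~4 (wide band: 12 replicates)
  expect_gt(v1 / v4, 1.5)
  expect_lt(v1 / v4, 11)
})

test_that("results are invariant under 2x voxel refinement within MC error", {
  m1 <- make_media_map(0.5e-3, dr = 10e-6, dz = 10e-6)
  m2 <- make_media_map(0.5e-3, dr = 5e-6, dz = 5e-6)
  t1 <- trace_segment(1, m1, n_photons = 2e4, seed = 5)$transmitted
  t2 <- trace_segment(1, m2, n_photons = 2e4, seed = 6)$transmitted
  expect_equal(t1, t2, tolerance = 0.02)
})

test_that("dynamic per-segment simulation conserves and partitions energy", {
  p <- make_power_profile(0.2, 70e-6)
  g <- make_bubble_geometry_sequence(0.5e-3, 1.5e-3)
  b <- run_dynamic_simulation(p, g, n_photons_per_segment = 2e3, seed = 2)
  expect_equal(b$fraction_fluid + b$fraction_solid + b$fraction_escaped, 1,
               tolerance = 1e-6)
  # Moses effect: the growing vapor channel delivers more energy to the stone
  # than bubble-free water would
  m <- make_media_map(0.5e-3)
  dm0 <- trace_segment(1, m, n_photons = 2e4, seed = 4)
  expect_gt(b$fraction_solid, dm0$transmitted)
  # both phases receive a nontrivial share (qualitative partition)
  expect_gt(b$fraction_fluid, 0.05)
  expect_gt(b$fraction_solid, 0.2)
})

test_that("segment count mismatch and missing seeds are rejected", {
  p <- make_power_profile(0.2, 70e-6)
  m <- make_media_map(0.5e-3)
  expect_error(trace_segment(1, m, n_photons = 10, seed = 1), "1000")
  expect_error(trace_segment(1, m, n_photons = 2000), "seed")
})
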