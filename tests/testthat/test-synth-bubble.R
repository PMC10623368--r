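test_that("bubble geometry sequence: inception, contact segment, final volume", {
  g <- make_bubble_geometry_sequence(0.5e-3, 1.5e-3)
  expect_equal(sum(g$masks[[1]]), 0)               # segment 0 pre-inception
  # apex reaches the stone surface at the default contact segment 5
  expect_lt(g$apex_depth[4], 0.5e-3)
  expect_equal(g$apex_depth[5], 0.5e-3)
  # final-segment volume-equivalent radius within 2% of Re_max (voxel sum)
  expect_equal(g$Re_per_segment[31], 1.5e-3, tolerance = 0.02)
})

test_that("vapor masks grow monotonically and are simply connected per column", {
  g <- make_bubble_geometry_sequence(0.4e-3, 1.2e-3, n_seg = 10L)
  for (s in 1:10) {
    prev <- g$masks[[s]]; cur <- g$masks[[s + 1]]
    expect_true(all(cur[prev]))  # nested growth
    # radial simple-connectedness: occupied cells in each column are a prefix
    for (j in seq_len(ncol(cur))) {
      occ <- which(cur[, j])
      if (length(occ)) expect_equal(occ, seq_len(max(occ)))
    }
  }
})

test_that("radius-time generator closes the loop with the energetics analyzer", {
  rt <- make_radius_time(1e-3, 90e-6, k1_target = 1.0, rebound_fraction = 0.3,
                         dt = 0.1e-6)
  be <- bubble_energetics(rt, SD = 0.5e-3)
  expect_equal(be$k1, 1.0, tolerance = 0.02)
  expect_equal(be$dEB / be$EB, 0.7, tolerance = 1e-3)  # EB ~ Re^3
  # growth phase monotone nondecreasing up to the labeled maximum
  grow <- rt$Re[rt$times <= rt$events[["maximum"]]]
  expect_true(all(diff(grow) >= -1e-12))
  expect_true(all(diff(rt$events) > 0))  # events ordered
})

test_that("radius-time generator rejects inconsistent timing and coarse sampling", {
  # k1 = 1 with t_max = 250 us would place the collapse before the maximum
  expect_error(make_radius_time(1e-3, 250e-6, 1.0, 0.3), "precede")
  expect_error(make_radius_time(1e-3, 90e-6, 1.0, 0.3, dt = 50e-6), "coarse")
  expect_error(make_radius_time(1e-3, 90e-6, 1.0, 1.5), "rebound_fraction")
})

test_that("silhouettes recover equivalent radii of known solids of revolution", {
  a <- 0.3e-3
  sph <- make_silhouette(function(z) sqrt(pmax(0, a^2 - (z - a)^2)),
                         z_extent = 2 * a, pixel_pitch = 10e-6)
  expect_equal(equivalent_radius(sph), a, tolerance = 0.02)
  aa <- 0.4e-3; bb <- 0.25e-3  # prolate spheroid: Re = (a b^2)^(1/3)
  spd <- make_silhouette(function(z) bb * sqrt(pmax(0, 1 - ((z - aa) / aa)^2)),
                         z_extent = 2 * aa, pixel_pitch = 10e-6)
  expect_equal(equivalent_radius(spd), (aa * bb^2)^(1 / 3), tolerance = 0.02)
})

test_that("silhouette generation is seed-deterministic and resolution-guarded", {
  a <- 0.3e-3
  prof <- function(z) sqrt(pmax(0, a^2 - (z - a)^2))
  s1 <- make_silhouette(prof, z_extent = 2 * a, pixel_pitch = 10e-6,
                        blur = 2, noise_sd = 0.01, seed = 9)
  s2 <- make_silhouette(prof, z_extent = 2 * a, pixel_pitch = 10e-6,
                        blur = 2, noise_sd = 0.01, seed = 9)
  expect_identical(s1$intensity, s2$intensity)
  expect_error(make_silhouette(prof, z_extent = 2 * a, pixel_pitch = 50e-6),
               "20 px")
})

test_that("pixel noise perturbs the extracted radius by less than 1%", {
  a <- 0.3e-3
  prof <- function(z) sqrt(pmax(0, a^2 - (z - a)^2))
  clean <- equivalent_radius(make_silhouette(prof, z_extent = 2 * a,
                                             pixel_pitch = 10e-6))
  for (s in 1:20) {
    noisy <- equivalent_radius(make_silhouette(prof, z_extent = 2 * a,
                                               pixel_pitch = 10e-6,
                                               noise_sd = 0.01, seed = s))
    expect_lt(abs(noisy - clean) / clean, 0.01)
  }
})
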