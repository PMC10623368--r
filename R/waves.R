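# Axisymmetric fluid-solid wave propagation from a monopole point source at
# height h_c above an elastic half-space: fluid pressure fields, boundary
# stress histories, leaky Rayleigh and Schmidt head waves.

#' Free-surface Rayleigh wave speed of an elastic solid
#'
#' Solves the Rayleigh characteristic equation
#' (2 - c^2/cT^2)^2 = 4 sqrt(1 - c^2/cL^2) sqrt(1 - c^2/cT^2) for the
#' surface-wave speed. The fluid-loaded (leaky) speed differs only weakly
#' for light fluid loading.
#'
#' @param solid elastic material record (rho, c_L, c_T).
#' @return m/s.
#' @export
rayleigh_wave_speed <- function(solid) {
  cT <- solid$c_T; cL <- solid$c_L
  f <- function(c) {
    (2 - c^2 / cT^2)^2 - 4 * sqrt(1 - c^2 / cL^2) * sqrt(1 - c^2 / cT^2)
  }
  uniroot(f, c(0.5 * cT, 0.999 * cT), tol = 1e-10)$root
}

#' Analytic Schmidt head-wave angle
#'
#' arcsin(c_fluid / c_R): the angle from the solid-surface normal at which
#' the leaky Rayleigh wave re-radiates into the fluid.
#'
#' @param fluid ambient fluid record.
#' @param solid elastic material record.
#' @return degrees.
#' @export
schmidt_angle_analytic <- function(fluid, solid) {
  cR <- rayleigh_wave_speed(solid)
  asin(fluid$c / cR) * 180 / pi
}

# material grids for the staggered solver; z runs downward, columns 1..nz_f
# are fluid, the rest solid (solid = NULL gives an all-fluid domain)
wave_grid <- function(fluid, solid, h, r_extent, z_fluid, z_solid) {
  nr <- ceiling(r_extent / h)
  nzf <- ceiling(z_fluid / h)
  nzs <- if (is.null(solid)) 0L else ceiling(z_solid / h)
  nz <- nzf + nzs
  lam <- matrix(fluid$rho * fluid$c^2, nr, nz)
  mu <- matrix(0, nr, nz)
  rho <- matrix(fluid$rho, nr, nz)
  if (nzs > 0L) {
    muS <- solid$rho * solid$c_T^2
    lamS <- solid$rho * solid$c_L^2 - 2 * muS
    cols <- (nzf + 1L):nz
    lam[, cols] <- lamS; mu[, cols] <- muS; rho[, cols] <- solid$rho
  }
  list(lambda = lam, mu = mu, rho = rho, nr = nr, nz = nz, nzf = nzf, h = h)
}

#' Build a calibrated monopole source
#'
#' The source is a single-cycle bipolar pulse of width `pulse_width`
#' injected as an isotropic stress increment at an on-axis fluid cell at
#' height `h_c` above the interface. Its amplitude is calibrated by a short
#' free-field (all-fluid) run on the same grid spacing so that the peak
#' free-field pressure extrapolated to 1 mm by the 1/r law equals
#' `peak_p_at_1mm` (the hydrophone-derived source strength; 30 bar at 1 mm
#' for the SD = 0.5 mm toroidal collapse).
#'
#' @param peak_p_at_1mm Pa.
#' @param pulse_width s (full bipolar cycle duration).
#' @param h_c source height above the solid surface, m.
#' @param h grid spacing of the intended simulation, m.
#' @param fluid ambient fluid record.
#' @param cfl Courant number used for calibration and simulation.
#' @param taper_factor moment-taper duration in units of `pulse_width`;
#'   longer tapers give a weaker rarefaction tail (relative amplitude about
#'   2/(pi*taper_factor)), mimicking the compression-dominant waveform of a
#'   collapse shock.
#' @param source_radius Gaussian radius of the injection blob, m; a fixed
#'   physical size makes results converge under grid refinement.
#' @return a `wave_source`: list(amplitude, pulse_width, h_c, peak_p_at_1mm,
#'   h, cfl, calibration = list(distance, peak)).
#' @export
build_source <- function(peak_p_at_1mm, pulse_width = 0.5e-6, h_c = 30e-6,
                         h = 10e-6, fluid = ambient_water(), cfl = 0.45,
                         taper_factor = 20, source_radius = 10e-6) {
  stopifnot_positive(peak_p_at_1mm = peak_p_at_1mm, pulse_width = pulse_width,
                     h_c = h_c, h = h)
  if (pulse_width < 8 * h / fluid$c)
    stop("pulse unresolvable on this grid: need pulse_width >= 8*h/c", call. = FALSE)
  # free-field calibration on a small all-fluid domain, at a fixed physical
  # distance so the calibrated amplitude is grid-independent
  d_cal <- 0.45e-3
  r_ext <- d_cal + max(0.25e-3, 40 * h)
  z_ext <- max(0.5e-3, 80 * h)
  g <- wave_grid(fluid, NULL, h, r_ext, z_ext, 0)
  dt <- cfl * h / (sqrt(2) * fluid$c)
  t_run <- d_cal / fluid$c + 2 * pulse_width
  nsteps <- ceiling(t_run / dt)
  src_j <- round(g$nz / 2)
  blob <- source_blob(g, src_j, source_radius, h)
  series <- source_series(1.0, pulse_width, dt, nsteps, taper_factor)
  st_i <- round(d_cal / h)
  out <- wave_sim_cpp(g$lambda, g$mu, g$rho, h, dt, nsteps,
                      blob$i - 1L, blob$j - 1L, blob$w,
                      series, as.integer(st_i - 1L), as.integer(src_j - 1L),
                      integer(0), 12L, 0.12, 0L)
  # (single station at the source row)
  p_tr <- -(out$st_srr[, 1] + out$st_stt[, 1] + out$st_szz[, 1]) / 3
  peak_meas <- max(abs(p_tr))
  d_act <- (st_i - 0.5) * h
  amplitude <- peak_p_at_1mm * 1e-3 / (peak_meas * d_act)
  structure(list(amplitude = amplitude, pulse_width = pulse_width, h_c = h_c,
                 peak_p_at_1mm = peak_p_at_1mm, h = h, cfl = cfl,
                 taper_factor = taper_factor, source_radius = source_radius,
                 calibration = list(distance = d_act, peak = peak_meas)),
            class = "wave_source")
}

# Gaussian injection blob around the on-axis cell at row src_j, truncated at
# 2.5 sigma; weights normalized against the ring volumes so the injected
# moment is grid-independent.
source_blob <- function(g, src_j, sigma_s, h, max_j = g$nz) {
  half <- max(1L, ceiling(2.5 * sigma_s / h))
  is <- integer(0); js <- integer(0); ws <- numeric(0)
  for (di in 0:half) {
    i <- 1L + di
    if (i > g$nr) next
    r_c <- (i - 0.5) * h
    for (dj in (-half):half) {
      j <- src_j + dj
      if (j < 1L || j > max_j) next  # keep the injection inside the fluid
      z_off <- dj * h
      d2 <- r_c^2 + z_off^2
      wgt <- exp(-d2 / (2 * sigma_s^2))
      if (wgt < 1e-3) next
      is <- c(is, i); js <- c(js, j); ws <- c(ws, wgt)
    }
  }
  list(i = is, j = js, w = ws / sum(ws * 2 * pi * (is - 0.5) * h^3) * 1e-15)
}

# Monopole injection series. The radiated far-field pressure follows the
# time derivative of the injected stress moment, so to radiate a
# compression-dominant shock (half-sine compression lobe of duration
# `pulse_width` followed by a weak, stretched rarefaction tail) the injected
# series is the running integral of that shape: a ramp up over the
# compression lobe, then a slow linear taper back to zero (taper 4x longer,
# giving a rarefaction tail of ~16% relative amplitude and a clean
# switch-off). Compression (p > 0) corresponds to negative injected stress.
source_series <- function(amplitude, pulse_width, dt, nsteps,
                          taper_factor = 4) {
  tt <- (seq_len(nsteps) - 0.5) * dt
  T1 <- pulse_width
  Tt <- taper_factor * T1
  W <- numeric(nsteps)
  ramp <- tt <= T1
  W[ramp] <- (1 - cos(pi * tt[ramp] / T1)) / 2   # integral of the half-sine lobe
  tap <- tt > T1 & tt <= T1 + Tt
  W[tap] <- 1 - (tt[tap] - T1) / Tt
  -amplitude * W
}

#' Simulate fluid-solid wave propagation from a monopole source
#'
#' Explicit velocity-stress staggered-grid finite differences in
#' axisymmetric (r, z); the fluid is the mu = 0 limit of the same scheme, so
#' interface conditions (continuous normal traction/velocity, zero shear)
#' hold without explicit coupling. Sponge layers absorb outgoing waves at
#' the outer boundaries.
#'
#' @param source a `wave_source` from [build_source()] (its grid spacing and
#'   Courant number are reused).
#' @param fluid ambient fluid record.
#' @param solid elastic material record, or NULL for a free-field fluid run.
#' @param r_extent,z_fluid,z_solid domain dimensions, m.
#' @param duration simulated time, s.
#' @param stations_r radial stations on the interface where solid-side
#'   stress histories are recorded, m.
#' @param gauges optional data.frame(r, height) of extra fluid gauge points
#'   (height above the interface, m; for all-fluid runs height is measured
#'   above the source row); their pressure traces are returned.
#' @param snapshot_times times at which fluid/solid pressure snapshots are
#'   stored, s.
#' @param sponge_cells,sponge_strength absorbing-layer controls.
#' @param energy_every record total discrete energy every k steps (0 = off);
#'   growth after source switch-off aborts with a diagnostic.
#' @return a `wave_result`: station principal-stress traces (sigma1, sigma3;
#'   Pa), times, snapshots (pressure matrices, nr x nz), grid metadata,
#'   energy series.
#' @export
simulate_waves <- function(source, fluid = ambient_water(),
                           solid = get_material("quartz", "elastic"),
                           r_extent = 2e-3, z_fluid = 1e-3, z_solid = 0.8e-3,
                           duration = 1e-6,
                           stations_r = seq(0.02e-3, 1.2e-3, by = 0.04e-3),
                           gauges = NULL, snapshot_times = numeric(0),
                           sponge_cells = 20L, sponge_strength = 0.10,
                           energy_every = 0L) {
  stopifnot(inherits(source, "wave_source"))
  h <- source$h
  g <- wave_grid(fluid, solid, h, r_extent, z_fluid, z_solid)
  c_max <- if (is.null(solid)) fluid$c else max(fluid$c, solid$c_L)
  dt <- source$cfl * h / (sqrt(2) * c_max)
  nsteps <- ceiling(duration / dt)
  # reference row: interface for fluid-solid runs, mid-depth for free field
  ref_j <- if (is.null(solid)) round(g$nzf / 2) else g$nzf
  # source cell: on-axis fluid cell centered closest to h_c above the reference
  src_j <- max(1L, min(g$nzf, round(ref_j + 0.5 - source$h_c / h)))
  blob <- source_blob(g, src_j, source$source_radius, h, max_j = g$nzf)
  series <- source_series(source$amplitude, source$pulse_width, dt, nsteps,
                          source$taper_factor)
  st_i <- pmax(1L, pmin(g$nr, round(stations_r / h + 0.5)))
  st_j <- rep(if (is.null(solid)) ref_j else g$nzf + 1L, length(st_i))
  n_station <- length(st_i)
  if (!is.null(gauges)) {
    gi <- pmax(1L, pmin(g$nr, round(gauges$r / h + 0.5)))
    gj <- pmax(1L, pmin(g$nz, round(ref_j + 0.5 - gauges$height / h)))
    st_i <- c(st_i, gi); st_j <- c(st_j, gj)
  }
  snap_steps <- sort(unique(pmax(1L, pmin(nsteps, round(snapshot_times / dt)))))
  if (length(snapshot_times) == 0) snap_steps <- integer(0)
  out <- wave_sim_cpp(g$lambda, g$mu, g$rho, h, dt, nsteps,
                      blob$i - 1L, blob$j - 1L, blob$w, series,
                      as.integer(st_i - 1L), as.integer(st_j - 1L),
                      as.integer(snap_steps), as.integer(sponge_cells),
                      sponge_strength, as.integer(energy_every))
  times <- seq_len(nsteps) * dt
  gauge_pressure <- NULL
  if (!is.null(gauges)) {
    gcols <- n_station + seq_len(nrow(gauges))
    gauge_pressure <- -(out$st_srr[, gcols, drop = FALSE] +
                          out$st_stt[, gcols, drop = FALSE] +
                          out$st_szz[, gcols, drop = FALSE]) / 3
    keep <- seq_len(n_station)
    out$st_srr <- out$st_srr[, keep, drop = FALSE]
    out$st_stt <- out$st_stt[, keep, drop = FALSE]
    out$st_szz <- out$st_szz[, keep, drop = FALSE]
    out$st_srz <- out$st_srz[, keep, drop = FALSE]
  }
  if (energy_every > 0 && length(out$energy) > 3) {
    e <- out$energy
    t_off <- (1 + source$taper_factor) * source$pulse_width
    i_off <- which(seq_along(e) * energy_every * dt > 1.05 * t_off)
    if (length(i_off) > 2) {
      e_off <- e[i_off]
      if (max(e_off) > 1.05 * e_off[1] && which.max(e_off) > 1)
        stop("instability detected: discrete energy grew after source switch-off",
             call. = FALSE)
    }
  }
  ps <- principal_stresses(out$st_srr, out$st_szz, out$st_stt, out$st_srz)
  structure(list(times = times, stations_r = (st_i - 0.5) * h,
                 sigma1 = ps$sigma1, sigma3 = ps$sigma3,
                 raw = list(srr = out$st_srr, stt = out$st_stt,
                            szz = out$st_szz, srz = out$st_srz),
                 snapshots = out$snapshots,
                 snapshot_times = snap_steps * dt,
                 gauges = gauges, gauge_pressure = gauge_pressure,
                 energy = out$energy, energy_every = energy_every, dt = dt,
                 grid = list(h = h, nr = g$nr, nz = g$nz, nzf = g$nzf),
                 source = source, fluid = fluid, solid = solid),
            class = "wave_result")
}

#' @method print wave_result
#' @export
print.wave_result <- function(x, ...) {
  cat(sprintf("<wave_result> %d steps of %.3g ns on a %d x %d grid (h = %.3g um)\n",
              length(x$times), x$dt * 1e9, x$grid$nr, x$grid$nz, x$grid$h * 1e6))
  if (length(x$stations_r))
    cat(sprintf("  %d interface stations to R = %.3g mm; peak sigma1 = %.4g MPa\n",
                length(x$stations_r), max(x$stations_r) * 1e3, max(x$sigma1) / 1e6))
  invisible(x)
}

#' Principal stresses of axisymmetric stress histories
#'
#' For the axisymmetric tensor (srr, szz, stt, srz) the hoop direction is
#' principal; the in-plane pair follows from the 2x2 eigenproblem. Returns
#' the sorted extremes: sigma1 = maximum (tension positive), sigma3 =
#' minimum.
#'
#' @param srr,szz,stt,srz stress components, Pa (vectors/matrices of equal
#'   shape).
#' @return list(sigma1, sigma3) matching the input shape.
#' @export
principal_stresses <- function(srr, szz, stt, srz) {
  m <- (srr + szz) / 2
  d <- sqrt(((srr - szz) / 2)^2 + srz^2)
  e1 <- m + d; e2 <- m - d
  list(sigma1 = pmax(e1, stt), sigma3 = pmin(e2, stt))
}

#' Extract the Schmidt head-wave angle from a snapshot
#'
#' In the radial window between the direct spherical wavefront and the
#' surface position of the leaky Rayleigh wave, the outermost fluid
#' disturbance at each height above the interface is the planar head-wave
#' front (the wave radiated by the faster surface wave). For each height row
#' the front position is located as the outermost threshold crossing of |p|
#' and a line is fitted; its inclination gives the propagation angle from
#' the surface normal, theta = asin(c_fluid/c_R).
#'
#' @param result a `wave_result` with at least one snapshot.
#' @param snapshot index of the snapshot to analyze (default the last).
#' @param min_height,max_height height band above the interface used for the
#'   front search, m (excludes interface-hugging leaky-wave fields and the
#'   region where the front merges with the direct wave).
#' @param threshold_fraction front detection level as a fraction of the row
#'   maximum inside the search window.
#' @return list(angle_deg, n_points, r, height) with the fitted front line.
#' @export
head_wave_angle <- function(result, snapshot = length(result$snapshots),
                            min_height = 0.15e-3, max_height = 1.2e-3,
                            lag = 5L) {
  if (length(result$snapshots) == 0) stop("no snapshots recorded", call. = FALSE)
  p <- result$snapshots[[snapshot]]
  t_snap <- result$snapshot_times[snapshot]
  h <- result$grid$h; nzf <- result$grid$nzf
  fl <- result$fluid
  cR <- rayleigh_wave_speed(result$solid)
  r_cols <- (seq_len(result$grid$nr) - 0.5) * h
  r_lo <- 1.15 * fl$c * t_snap
  r_hi <- 0.90 * cR * t_snap
  use <- which(r_cols > r_lo & r_cols < r_hi)
  if (length(use) < 8) stop("head wave not separated; run longer or enlarge the domain",
                            call. = FALSE)
  heights <- (nzf - (seq_len(nzf) - 0.5)) * h  # height above interface per fluid row
  rows <- which(heights > min_height & heights < max_height)
  crest_h <- rep(NA_real_, length(use)); crest_p <- rep(NA_real_, length(use))
  for (k in seq_along(use)) {
    col <- abs(p[use[k], rows])
    j <- which.max(col)
    pk <- parabolic_peak(heights[rows], col, j)
    crest_h[k] <- pk$x; crest_p[k] <- pk$y
  }
  good <- which(crest_p > 0.1 * stats::median(crest_p, na.rm = TRUE) & !is.na(crest_h))
  if (length(good) < 3 * lag) stop("head-wave front not detected", call. = FALSE)
  x <- r_cols[use][good]; y <- crest_h[good]
  # Theil-Sen over a fixed column lag: robust to jumps between the bipolar
  # lobes of the front (parallel crest lines)
  n <- length(x)
  i <- seq_len(n - lag)
  slopes <- (y[i + lag] - y[i]) / (x[i + lag] - x[i])
  slope <- stats::median(slopes)
  list(angle_deg = atan(abs(slope)) * 180 / pi, n_points = n,
       r = x, height = y)
}
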