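# Bubble kinematics and acoustic-emission metrics: equivalent radius from
# silhouettes, dimensionless standoff gamma, Rayleigh-normalized collapse
# times (prolongation factor k1), bubble potential energies, significant
# acoustic peaks with 1/r scaling, pressure impulse, acoustic emission
# energy, toroidal-bubble geometry and collision speed.

#' Equivalent radius from a silhouette image
#'
#' The silhouette is thresholded to binary, each pixel row (perpendicular to
#' the symmetry axis) contributes a disk of radius half its occupied width,
#' and the solid-of-revolution volume gives Re = (3V/4pi)^(1/3).
#'
#' @param sil a `silhouette_image`.
#' @return m. An empty silhouette returns 0 with a warning.
#' @export
equivalent_radius <- function(sil) {
  stopifnot(inherits(sil, "silhouette_image"))
  bin <- sil$intensity >= sil$threshold
  counts <- rowSums(bin)
  if (sum(counts) == 0) {
    warning("empty silhouette; returning 0", call. = FALSE)
    return(0)
  }
  pitch <- sil$pixel_pitch
  r_rows <- counts * pitch / 2
  V <- sum(pi * r_rows^2) * pitch
  (3 * V / (4 * pi))^(1 / 3)
}

#' Bubble energetics from a labeled radius-time series
#'
#' Computes the dimensionless standoff gamma = SD/Re_max, the Rayleigh
#' collapse time Tc = 0.915 Re_max sqrt(rho/(p_stat - p_v)), the prolongation
#' factor k1 = t1/(2 Tc) (t1: inception to primary collapse), the maximum
#' bubble potential energy EB = (4pi/3)(p_stat - p_v) Re_max^3, the rebound
#' potential energy EB1 and the collapse loss dEB = EB - EB1.
#'
#' @param series a `radius_time_series` with labeled events (inception,
#'   maximum, primary_collapse, rebound_max).
#' @param SD standoff distance, m.
#' @param fluid ambient fluid record.
#' @return a `bubble_energetics` list: Re_max, gamma, Tc, k1, EB, EB1, dEB
#'   (SI units).
#' @export
bubble_energetics <- function(series, SD, fluid = ambient_water()) {
  stopifnot(inherits(series, "radius_time_series"))
  need <- c("inception", "maximum", "primary_collapse", "rebound_max")
  if (!all(need %in% names(series$events)))
    stop("series must carry labeled events: ", paste(need, collapse = ", "), call. = FALSE)
  ev <- series$events
  Re_max <- max(series$Re[series$times <= ev[["primary_collapse"]]])
  dp <- fluid$p_stat - fluid$p_v
  Tc <- rayleigh_collapse_time(Re_max, fluid)
  t1 <- ev[["primary_collapse"]] - ev[["inception"]]
  k1 <- t1 / (2 * Tc)
  EB <- 4 * pi / 3 * dp * Re_max^3
  # rebound maximum radius in a window around the labeled rebound event
  post <- series$times > ev[["primary_collapse"]]
  R2 <- if (any(post)) max(series$Re[post]) else 0
  EB1 <- 4 * pi / 3 * dp * R2^3
  structure(list(Re_max = Re_max, gamma = SD / Re_max, Tc = Tc, k1 = k1,
                 EB = EB, EB1 = EB1, dEB = EB - EB1),
            class = "bubble_energetics")
}

#' @method print bubble_energetics
#' @export
print.bubble_energetics <- function(x, ...) {
  cat(sprintf("<bubble_energetics> Re_max = %.3g mm, gamma = %.3g, Tc = %.3g us, k1 = %.3g\n",
              x$Re_max * 1e3, x$gamma, x$Tc * 1e6, x$k1))
  cat(sprintf("  EB = %.3g J, EB1 = %.3g J, dEB/EB = %.3g\n", x$EB, x$EB1, x$dEB / x$EB))
  invisible(x)
}

#' Detect significant pressure peaks in a hydrophone trace
#'
#' Local maxima with prominence above 3x the trace noise RMS are candidate
#' peaks; a peak is significant when its pressure is strictly larger than
#' 30% of the maximum pressure in the trace.
#'
#' @param trace a `hydrophone_trace` (or list with times/pressure and
#'   sensor_distance).
#' @param threshold_fraction significance threshold as a fraction of the
#'   trace maximum (0.3, the conventional selection rule).
#' @param min_prominence minimum peak prominence, Pa; default 3x noise RMS.
#' @return an `acoustic_peaks` data.frame: time, pressure (at sensor),
#'   pressure_1mm (1/r-scaled), significant.
#' @export
detect_significant_peaks <- function(trace, threshold_fraction = 0.3,
                                     min_prominence = NULL) {
  p <- trace$pressure
  if (length(p) == 0 || all(p == 0))
    return(structure(data.frame(time = numeric(0), pressure = numeric(0),
                                pressure_1mm = numeric(0), significant = logical(0)),
                     class = c("acoustic_peaks", "data.frame")))
  if (is.null(min_prominence))
    min_prominence <- 3 * (if (!is.null(trace$noise_rms)) trace$noise_rms else 0)
  n <- length(p)
  is_max <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n], FALSE)
  idx <- which(is_max & p > min_prominence)
  if (length(idx) > 0) {
    # prominence relative to the deepest saddle toward a higher neighbor peak
    keep <- vapply(idx, function(i) {
      higher <- idx[p[idx] > p[i]]
      if (length(higher) == 0) return(TRUE)
      j <- higher[which.min(abs(higher - i))]
      saddle <- min(p[min(i, j):max(i, j)])
      (p[i] - saddle) >= min_prominence
    }, logical(1))
    idx <- idx[keep]
  }
  pk_t <- trace$times[idx]; pk_p <- p[idx]
  thr <- threshold_fraction * max(p)
  out <- data.frame(time = pk_t, pressure = pk_p,
                    pressure_1mm = scale_to_1mm(pk_p, trace$sensor_distance),
                    significant = pk_p > thr)  # strict inequality
  structure(out, class = c("acoustic_peaks", "data.frame"))
}

#' Scale a measured pressure to 1 mm from the source
#'
#' Spherically diverging shock: p(r) ~ 1/r, so the 1 mm-referenced value is
#' p * (sensor_distance / 1 mm).
#'
#' @param pressure Pa.
#' @param sensor_distance m, > 0.
#' @return Pa at 1 mm.
#' @export
scale_to_1mm <- function(pressure, sensor_distance) {
  stopifnot_positive(sensor_distance = sensor_distance)
  pressure * (sensor_distance / 1e-3)
}

#' Pressure impulse over a time window
#'
#' @param trace a `hydrophone_trace`.
#' @param window c(t0, t1), s, inside the trace support.
#' @return Pa*s, trapezoidal integral of pressure over the window.
#' @export
pressure_impulse <- function(trace, window = range(trace$times)) {
  t0 <- window[1]; t1 <- window[2]
  if (t0 < min(trace$times) || t1 > max(trace$times))
    stop("window outside the trace support", call. = FALSE)
  sel <- trace$times >= t0 & trace$times <= t1
  if (sum(sel) < 2) {
    warning("empty integration window; returning 0", call. = FALSE)
    return(0)
  }
  trapz(trace$times[sel], trace$pressure[sel])
}

#' Acoustic emission energy of a burst
#'
#' Far-field spherical-wave energy Es = (4 pi r^2 / (rho c)) * integral p^2 dt
#' over the burst window, with r the sensor distance. Consistent with the
#' 1/r amplitude convention: Es is independent of the sensor distance when
#' the trace follows spherical spreading.
#'
#' @param trace a `hydrophone_trace` (sensor_distance required).
#' @param fluid ambient fluid record.
#' @param window c(t0, t1), s; default the whole trace.
#' @return J.
#' @export
acoustic_emission_energy <- function(trace, fluid = ambient_water(),
                                     window = range(trace$times)) {
  r <- trace$sensor_distance
  stopifnot_positive(sensor_distance = r)
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(sel) < 2) return(0)
  4 * pi * r^2 / (fluid$rho * fluid$c) *
    trapz(trace$times[sel], trace$pressure[sel]^2)
}

#' Emission metrics of a two-burst collapse trace
#'
#' Splits the trace at `t_split` (the rebound-maximum time) into the primary
#' and secondary collapse windows and reports the 1 mm-scaled maximum peak
#' pressures p1, p2, their ratio, the pressure impulse and the acoustic
#' emission energies of both bursts.
#'
#' @param trace a `hydrophone_trace`.
#' @param t_split s, boundary between primary and secondary burst windows.
#' @param fluid ambient fluid record.
#' @return an `emission_metrics` list: p1, p2 (Pa at 1 mm), p1_over_p2,
#'   PI (Pa*s over the primary window), Es1, Es2 (J).
#' @export
emission_metrics <- function(trace, t_split, fluid = ambient_water()) {
  peaks <- detect_significant_peaks(trace)
  prim <- peaks[peaks$time <= t_split, , drop = FALSE]
  sec <- peaks[peaks$time > t_split, , drop = FALSE]
  p1 <- if (nrow(prim)) max(prim$pressure_1mm) else 0
  p2 <- if (nrow(sec)) max(sec$pressure_1mm) else 0
  w1 <- c(min(trace$times), t_split)
  w2 <- c(t_split, max(trace$times))
  structure(list(p1 = p1, p2 = p2,
                 p1_over_p2 = if (p2 > 0) p1 / p2 else NA_real_,
                 PI = pressure_impulse(trace, w1),
                 Es1 = acoustic_emission_energy(trace, fluid, w1),
                 Es2 = acoustic_emission_energy(trace, fluid, w2)),
            class = "emission_metrics")
}

#' Toroidal bubble volume
#'
#' V = 2 pi^2 r_c r_torus^2 for a circular-cross-section torus of centerline
#' radius r_c and cross-section radius r_torus.
#'
#' @param r_c centerline radius, m.
#' @param r_torus cross-section radius, m (<= r_c).
#' @return m^3.
#' @export
torus_volume <- function(r_c, r_torus) {
  stopifnot_positive(r_c = r_c)
  stopifnot_nonneg(r_torus = r_torus)
  if (r_torus > r_c) stop("r_torus must not exceed r_c", call. = FALSE)
  2 * pi^2 * r_c * r_torus^2
}

#' Volumetric compression ratio of the toroidal collapse
#'
#' @param max_state,min_state lists with r_c and r_torus (m) at maximum and
#'   minimum torus volume.
#' @return dimensionless V_max / V_min.
#' @export
compression_ratio <- function(max_state, min_state) {
  torus_volume(max_state$r_c, max_state$r_torus) /
    torus_volume(min_state$r_c, min_state$r_torus)
}

#' Collision speed of the toroidal bubble walls
#'
#' The closure speed on the boundary is the sum of the inward contraction of
#' the outer bubble wall and the outward radial jetting flow.
#'
#' @param v_contraction m/s.
#' @param v_radial_jet m/s.
#' @return m/s.
#' @export
collision_speed <- function(v_contraction, v_radial_jet) {
  stopifnot_nonneg(v_contraction = v_contraction, v_radial_jet = v_radial_jet)
  v_contraction + v_radial_jet
}

#' Shock Mach number
#'
#' @param shock_speed m/s (e.g. 1820 measured near the quartz boundary).
#' @param c sound speed of the fluid, m/s (1480 at 20 C).
#' @return dimensionless Ma = v/c.
#' @export
mach_number <- function(shock_speed, c = ambient_water()$c) {
  stopifnot_positive(shock_speed = shock_speed, c = c)
  shock_speed / c
}
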