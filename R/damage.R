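# Tuler-Butcher cumulative damage assessment of boundary stress histories:
# stress integral SI, peak tensile/compressive profiles, -6 dB widths,
# h_c / SD sweeps, threshold comparison.

#' Tuler-Butcher stress integral
#'
#' SI = integral of (sigma_T - sigma_0)^2 dt over the samples where
#' sigma_T > sigma_0 (strict), with sigma_T the maximum principal (tensile)
#' stress history and sigma_0 the material damage threshold stress
#' (7.1 MPa for hard BegoStone).
#'
#' @param sigma1_trace Pa, uniformly sampled tensile stress history.
#' @param times s (same length), or a scalar sampling interval.
#' @param sigma0 Pa.
#' @return Pa^2*s.
#' @export
stress_integral <- function(sigma1_trace, times, sigma0 = 7.1e6) {
  if (length(times) == 1L) times <- seq_along(sigma1_trace) * times
  excess <- ifelse(sigma1_trace > sigma0, (sigma1_trace - sigma0)^2, 0)
  trapz(times, excess)
}

#' BegoStone damage threshold band
#'
#' @param lower,upper Pa^2*s (hard BegoStone: 6.7e8 to 8.8e8).
#' @return a `threshold_band`.
#' @export
threshold_band <- function(lower = 6.7e8, upper = 8.8e8) {
  if (lower > upper) stop("lower must not exceed upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "threshold_band")
}

#' Classify a stress integral against the damage threshold band
#'
#' @param SI_max Pa^2*s.
#' @param band a `threshold_band`.
#' @return list(class = "below"|"within"|"above", ratio = SI_max / lower
#'   edge).
#' @export
classify_damage <- function(SI_max, band = threshold_band()) {
  stopifnot_nonneg(SI_max = SI_max)
  cls <- if (SI_max < band$lower) "below" else if (SI_max > band$upper) "above" else "within"
  list(class = cls, ratio = SI_max / band$lower)
}

# -6 dB (half-extremum) width of a sampled radial profile by linear
# interpolation of the half-level crossings around the extremum
half_width_of_profile <- function(r, v) {
  i <- which.max(v)
  pk <- parabolic_peak(r, v, i)
  half <- pk$y / 2
  left <- NA_real_; right <- NA_real_
  if (i > 1) {
    below <- which(v[1:(i - 1)] < half)
    if (length(below)) {
      j <- max(below)
      left <- approx(v[c(j, j + 1)], r[c(j, j + 1)], xout = half)$y
    }
  }
  n <- length(r)
  if (i < n) {
    below <- which(v[(i + 1):n] < half)
    if (length(below)) {
      j <- i + min(below)
      right <- approx(v[c(j - 1, j)], r[c(j - 1, j)], xout = half)$y
    }
  }
  list(width = right - left, left = left, right = right,
       location = pk$x, extremum = pk$y,
       resolved = is.finite(left) && is.finite(right))
}

#' Damage metrics from a set of boundary stress traces
#'
#' Reduces interface sigma1/sigma3 histories at radial stations to: the
#' maximum stress integral and its location, the peak tensile stress
#' (sigma1_max) and peak compression (sigma3_min) with locations
#' (parabolic sub-station interpolation), and the -6 dB (half-extremum)
#' radial widths of both profiles.
#'
#' @param result a `wave_result` (station traces), or a list with `times`,
#'   `stations_r`, `sigma1`, `sigma3` matrices (time x station).
#' @param sigma0 Pa, Tuler-Butcher threshold stress.
#' @return a `damage_metrics` list: SI_max, SI_location, SI_profile,
#'   sigma1_max, sigma1_location, width_6dB_tension, sigma3_min,
#'   sigma3_location, width_6dB_compression, tension_present, flags.
#' @export
boundary_profiles <- function(result, sigma0 = 7.1e6) {
  r <- result$stations_r
  if (length(r) < 3) stop("need at least 3 radial stations", call. = FALSE)
  s1max <- apply(result$sigma1, 2, max)
  s3min <- apply(result$sigma3, 2, min)
  SI <- vapply(seq_along(r), function(k)
    stress_integral(result$sigma1[, k], result$times, sigma0), numeric(1))
  tension_present <- any(s1max > 0)
  flags <- character(0)
  out <- list(SI_profile = SI, stations_r = r, sigma0 = sigma0,
              tension_present = tension_present)
  if (tension_present) {
    wt <- half_width_of_profile(r, s1max)
    out$sigma1_max <- wt$extremum
    out$sigma1_location <- wt$location
    out$width_6dB_tension <- wt$width
    if (!wt$resolved) flags <- c(flags, "tension extremum or width at station-range edge")
    iSI <- which.max(SI)
    pkSI <- parabolic_peak(r, SI, iSI)
    out$SI_max <- max(pkSI$y, 0)
    out$SI_location <- pkSI$x
    if (iSI %in% c(1L, length(r))) flags <- c(flags, "SI extremum at station-range edge")
  } else {
    out$sigma1_max <- NA_real_; out$sigma1_location <- NA_real_
    out$width_6dB_tension <- NA_real_
    out$SI_max <- 0; out$SI_location <- NA_real_
  }
  wc <- half_width_of_profile(r, -s3min)
  out$sigma3_min <- -wc$extremum
  out$sigma3_location <- wc$location
  out$width_6dB_compression <- wc$width
  if (!wc$resolved) flags <- c(flags, "compression width at station-range edge")
  out$flags <- flags
  structure(out, class = "damage_metrics")
}

#' @method print damage_metrics
#' @export
print.damage_metrics <- function(x, ...) {
  if (x$tension_present) {
    cat(sprintf("<damage_metrics> SI_max = %.4g Pa^2 s at R = %.3g mm\n",
                x$SI_max, x$SI_location * 1e3))
    cat(sprintf("  sigma1_max = %.4g MPa at R = %.3g mm (-6 dB width %.3g mm)\n",
                x$sigma1_max / 1e6, x$sigma1_location * 1e3,
                x$width_6dB_tension * 1e3))
  } else {
    cat("<damage_metrics> no tensile excursion on the boundary\n")
  }
  cat(sprintf("  sigma3_min = %.4g MPa at R = %.3g mm\n",
              x$sigma3_min / 1e6, x$sigma3_location * 1e3))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Default source peak pressure (at 1 mm) per standoff distance
#'
#' Hydrophone-derived peak pressures of the primary toroidal-bubble collapse
#' used as canonical source amplitudes: 30 bar at SD = 0.5 mm, decreasing
#' steeply with SD (log-linear interpolation between the measured 30 bar at
#' 0.5 mm and 0.25 bar at 1.5 mm).
#'
#' @param SD standoff distance, m.
#' @return Pa.
#' @export
source_peak_for_sd <- function(SD) {
  sd_mm <- SD * 1e3
  1e5 * exp(approx(c(0.5, 1.5), log(c(30, 0.25)), xout = sd_mm, rule = 2)$y)
}

#' Sweep the damage metrics over collapse height and standoff distance
#'
#' Runs the fluid-solid wave simulation for each (SD, h_c) pair, with the
#' source amplitude set by the measured peak-pressure trend per SD, and
#' collects the resulting damage metrics.
#'
#' @param h_c_values collapse heights above the boundary, m.
#' @param SD_values standoff distances, m.
#' @param solid elastic material record for the stone.
#' @param sigma0 Pa, Tuler-Butcher threshold.
#' @param h grid spacing, m.
#' @param r_extent,z_fluid,z_solid,duration domain/time controls (see
#'   [simulate_waves()]).
#' @param stations_r interface stations, m.
#' @param peak_fun function(SD) giving the source peak at 1 mm, Pa.
#' @return data.frame(SD, h_c, SI_max, sigma1_max, sigma3_min, ...) one row
#'   per combination.
#' @export
sweep_hc <- function(h_c_values, SD_values = 0.5e-3,
                     solid = get_material("begostone", "elastic"),
                     sigma0 = 7.1e6, h = 10e-6,
                     r_extent = 1.6e-3, z_fluid = 0.7e-3, z_solid = 0.6e-3,
                     duration = 1.1e-6,
                     stations_r = seq(0.02e-3, 1.2e-3, by = 0.04e-3),
                     peak_fun = source_peak_for_sd) {
  if (length(h_c_values) < 1) stop("need at least one h_c value", call. = FALSE)
  rows <- list()
  for (SD in SD_values) {
    peak <- peak_fun(SD)
    for (hc in h_c_values) {
      src <- build_source(peak_p_at_1mm = peak, h_c = hc, h = h)
      res <- simulate_waves(src, solid = solid, r_extent = r_extent,
                            z_fluid = z_fluid, z_solid = z_solid,
                            duration = duration, stations_r = stations_r)
      dm <- boundary_profiles(res, sigma0 = sigma0)
      rows[[length(rows) + 1L]] <- data.frame(
        SD = SD, h_c = hc, SI_max = dm$SI_max,
        SI_location = if (is.null(dm$SI_location)) NA_real_ else dm$SI_location,
        sigma1_max = dm$sigma1_max, sigma1_location = dm$sigma1_location,
        sigma3_min = dm$sigma3_min, sigma3_location = dm$sigma3_location)
    }
  }
  do.call(rbind, rows)
}
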