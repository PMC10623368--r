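# Synthetic hydrophone traces: multi-peak shock bursts as recorded by a
# needle hydrophone at a known distance from the collapse site.

#' Generate a synthetic hydrophone trace
#'
#' Each requested shock is rendered as a short bipolar transient (one sine
#' cycle, 0.5 us half-width by default) whose positive crest equals the
#' requested amplitude at 1 mm scaled by the spherical-spreading factor
#' (1 mm / sensor_distance). Amplitudes superpose where supports overlap
#' (with a warning). Gaussian sensor noise is added under a fixed seed.
#'
#' @param peak_list data.frame or matrix with columns `time` (s) and `p_1mm`
#'   (Pa, peak pressure referenced to 1 mm from the source).
#' @param sensor_distance m, > 0 (10 mm in the experimental layout).
#' @param noise_rms Pa, RMS of additive Gaussian noise (0 = clean).
#' @param seed RNG seed; traces are bit-identical under the same seed.
#' @param fs sampling rate, Hz.
#' @param half_width s, duration of each polarity lobe.
#' @param t_end s, trace duration (default: last peak + 20 us).
#' @return a `hydrophone_trace`: list(times, pressure, sensor_distance,
#'   noise_rms, fs).
#' @export
make_hydrophone_trace <- function(peak_list, sensor_distance = 10e-3,
                                  noise_rms = 0, seed = 1L, fs = 10e6,
                                  half_width = 0.5e-6, t_end = NULL) {
  stopifnot_positive(sensor_distance = sensor_distance, fs = fs,
                     half_width = half_width)
  pk <- as.data.frame(peak_list)
  stopifnot(all(c("time", "p_1mm") %in% names(pk)))
  period <- 2 * half_width
  if (nrow(pk) > 1L) {
    gaps <- diff(sort(pk$time))
    if (any(gaps < period))
      warning("peak supports overlap; amplitudes superpose", call. = FALSE)
  }
  if (is.null(t_end)) t_end <- max(pk$time) + 20e-6
  dt <- 1 / fs
  times <- seq(0, t_end, by = dt)
  pressure <- numeric(length(times))
  scale <- 1e-3 / sensor_distance
  for (i in seq_len(nrow(pk))) {
    A <- pk$p_1mm[i] * scale
    # crest aligned exactly on the requested peak time
    tau <- times - pk$time[i] + period / 4
    lobe <- tau >= 0 & tau <= period
    pressure[lobe] <- pressure[lobe] + A * sin(2 * pi * tau[lobe] / period)
  }
  if (noise_rms > 0) {
    set.seed(as.integer(seed))
    pressure <- pressure + rnorm(length(pressure), sd = noise_rms)
  }
  structure(list(times = times, pressure = pressure,
                 sensor_distance = sensor_distance, noise_rms = noise_rms,
                 fs = fs),
            class = "hydrophone_trace")
}

#' @method print hydrophone_trace
#' @export
print.hydrophone_trace <- function(x, ...) {
  cat(sprintf("<hydrophone_trace> %d samples at %.3g MHz, sensor at %.3g mm\n",
              length(x$times), x$fs / 1e6, x$sensor_distance * 1e3))
  cat(sprintf("  max |p| = %.4g Pa, noise RMS = %.3g Pa\n",
              max(abs(x$pressure)), x$noise_rms))
  invisible(x)
}

#' @method plot hydrophone_trace
#' @export
plot.hydrophone_trace <- function(x, ...) {
  graphics::plot(x$times * 1e6, x$pressure / 1e5, type = "l",
                 xlab = "time (us)", ylab = "pressure (bar)", ...)
  invisible(x)
}
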