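# Synthetic laser pulse power profiles.
#
# The dusting setting of a Ho:YAG lithotripter delivers Ep = 0.2 J over a
# ~150 us pulse with 70 us FWHM. The measured profile is not published in
# tabulated form, so the default synthetic shape is a trapezoid-with-tail:
# 10 us linear rise, flat top, 10 us fall to a low shelf that persists to the
# end of the support, with the fall timed so the FWHM is exact.

#' Generate a synthetic laser power profile
#'
#' @param Ep pulse energy, J.
#' @param fwhm full width at half maximum, s.
#' @param shape "trapezoid" (ramp/plateau/ramp-down to a low shelf, the
#'   default emulation of the measured dusting profile), "flat" (rectangle of
#'   duration `fwhm`) or "ramped" (symmetric triangle).
#' @param dt sample spacing, s; must resolve the pulse (dt < fwhm/10).
#' @param support total temporal support, s (trapezoid shape only; default
#'   150 us as used for 30 x 5 us segmentation).
#' @param shelf_fraction trapezoid tail shelf power as a fraction of peak.
#' @return a `laser_pulse`: list with `times` (s), `power` (W), `Ep`, `fwhm`,
#'   `fiber_core_diameter` (m), `numerical_aperture`. The trapezoidal
#'   integral of `power` equals `Ep` to 0.1% and the realized FWHM matches
#'   the request to 2%.
#' @export
make_power_profile <- function(Ep, fwhm, shape = c("trapezoid", "flat", "ramped"),
                               dt = 0.5e-6, support = 150e-6,
                               shelf_fraction = 0.2,
                               fiber_core_diameter = 365e-6,
                               numerical_aperture = 0.26) {
  shape <- match.arg(shape)
  stopifnot_positive(Ep = Ep, fwhm = fwhm, dt = dt)
  if (dt >= fwhm / 10) stop("dt must be finer than fwhm/10 to resolve the pulse", call. = FALSE)

  if (shape == "flat") {
    support_eff <- fwhm
    times <- seq(0, support_eff, by = dt)
    shape_fun <- function(t) as.numeric(t >= 0 & t <= fwhm)
  } else if (shape == "ramped") {
    support_eff <- 2 * fwhm
    times <- seq(0, support_eff, by = dt)
    shape_fun <- function(t) pmax(0, 1 - abs(t - fwhm) / fwhm)
  } else {
    if (support <= fwhm + 10e-6) stop("support too short for the requested FWHM", call. = FALSE)
    q <- shelf_fraction
    ramp <- 10e-6
    # down-ramp start such that the half-max crossing sits at ramp/2 + fwhm
    t_down <- ramp / 2 + fwhm - ramp / (2 * (1 - q))
    if (t_down <= ramp) stop("fwhm too short for the trapezoid shape", call. = FALSE)
    support_eff <- support
    times <- seq(0, support_eff, by = dt)
    shape_fun <- function(t) {
      ifelse(t < ramp, t / ramp,
        ifelse(t <= t_down, 1,
          ifelse(t <= t_down + ramp, 1 - (1 - q) * (t - t_down) / ramp,
            ifelse(t <= support_eff, q, 0))))
    }
  }
  power <- shape_fun(times)
  power <- power * (Ep / trapz(times, power))
  pulse <- structure(list(times = times, power = power, Ep = Ep, fwhm = fwhm,
                          shape = shape,
                          fiber_core_diameter = fiber_core_diameter,
                          numerical_aperture = numerical_aperture),
                     class = "laser_pulse")
  realized <- profile_fwhm(times, power)
  if (abs(realized - fwhm) / fwhm > 0.02)
    stop(sprintf("realized FWHM %.3g s deviates more than 2%% from request %.3g s",
                 realized, fwhm), call. = FALSE)
  pulse
}

#' Partition a pulse into equal-duration segment energies
#'
#' Used to drive the per-segment Monte Carlo transport: the pulse support is
#' cut into `n_seg` even segments (5 us each for the default 150 us pulse)
#' and the energy of each is the trapezoidal integral over the sub-interval.
#' The segment energies sum to the pulse energy exactly (partition of the
#' integral).
#'
#' @param pulse a `laser_pulse`.
#' @param n_seg number of segments.
#' @return numeric vector of segment energies, J.
#' @export
segment_energies <- function(pulse, n_seg = 30L) {
  stopifnot(inherits(pulse, "laser_pulse"))
  tmax <- max(pulse$times)
  edges <- seq(0, tmax, length.out = n_seg + 1L)
  vapply(seq_len(n_seg), function(i) {
    # integrate on a refined common grid so segments tile the support exactly
    tt <- unique(sort(c(edges[i], edges[i + 1L],
                        pulse$times[pulse$times >= edges[i] & pulse$times <= edges[i + 1L]])))
    pp <- approx(pulse$times, pulse$power, xout = tt, rule = 2)$y
    trapz(tt, pp)
  }, numeric(1))
}

#' @method print laser_pulse
#' @export
print.laser_pulse <- function(x, ...) {
  cat(sprintf("<laser_pulse> Ep = %.3g J, FWHM = %.3g us (%s), %d samples over %.3g us\n",
              x$Ep, x$fwhm * 1e6, x$shape, length(x$times), max(x$times) * 1e6))
  cat(sprintf("  peak power %.4g W; fiber core %.0f um, NA = %.2f\n",
              max(x$power), x$fiber_core_diameter * 1e6, x$numerical_aperture))
  invisible(x)
}

#' @method plot laser_pulse
#' @export
plot.laser_pulse <- function(x, ...) {
  graphics::plot(x$times * 1e6, x$power, type = "l", xlab = "time (us)",
                 ylab = "power (W)", main = "Laser pulse power profile", ...)
  invisible(x)
}
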