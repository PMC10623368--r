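#' @useDynLib lithocav, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx uniroot optimize rnorm runif
#' @importFrom utils head tail
NULL

# trapezoidal quadrature on possibly non-uniform abscissae
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

stopifnot_positive <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("'%s' must be a positive finite number", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

stopifnot_nonneg <- function(...) {
  args <- list(...)
  nm <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("'%s' must be a non-negative finite number", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Full width at half maximum of a sampled profile, by linear interpolation of
# the half-maximum crossings around the first/last samples above half max.
profile_fwhm <- function(times, power) {
  pm <- max(power)
  if (pm <= 0) return(0)
  half <- pm / 2
  above <- which(power >= half)
  i1 <- above[1]; i2 <- above[length(above)]
  t_lo <- if (i1 == 1L) times[1] else {
    approx(power[c(i1 - 1L, i1)], times[c(i1 - 1L, i1)], xout = half)$y
  }
  t_hi <- if (i2 == length(times)) times[i2] else {
    approx(power[c(i2, i2 + 1L)], times[c(i2, i2 + 1L)], xout = half)$y
  }
  t_hi - t_lo
}

# Deterministic fan-out of one user seed into per-stage seeds (kept < 2^31).
derive_seed <- function(seed, stage) {
  offsets <- c(pulse = 11L, geometry = 23L, radius = 37L, trace = 53L,
               silhouette = 71L, mc = 97L, thermal = 113L, waves = 131L,
               pipeline = 151L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# parabolic (three-point) interpolation of an extremum location
parabolic_peak <- function(x, y, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(list(x = x[i], y = y[i]))
  d <- (y[i - 1L] - 2 * y[i] + y[i + 1L])
  if (d == 0) return(list(x = x[i], y = y[i]))
  h <- (x[i + 1L] - x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / d
  list(x = x[i] + delta * h, y = y[i] - 0.25 * (y[i - 1L] - y[i + 1L]) * delta)
}
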