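# Axisymmetric transient heat conduction with melting-threshold ablation.
#
# rho*Cp dT/dt - k laplacian(T) = f on a cell-centered (r, z) grid,
# discretized in conservative finite-volume form (cell centres at
# r_i = (i - 1/2) dr so the axis is a natural zero-flux face) and stepped
# implicitly (theta-scheme; backward Euler theta = 1 is unconditionally
# stable, Crank-Nicolson theta = 0.5 is second order). Homogeneous Neumann
# boundaries everywhere, matching a thermally insulated block irradiated
# from the top.

#' Create an axisymmetric thermal field
#'
#' @param medium a thermal material record (see [get_material()]).
#' @param extent list(r, z) domain extents, m (default the 0.5 x 0.5 mm
#'   solid block used for crater simulations).
#' @param n list(r, z) cell counts.
#' @param T0 initial uniform temperature, K.
#' @return a `thermal_field`: temperature matrix (nr x nz; column 1 is the
#'   irradiated top surface), ablated mask, accumulated deposited energy per
#'   cell, grid spec and medium.
#' @export
thermal_field <- function(medium = get_material("begostone", "thermal"),
                          extent = list(r = 0.5e-3, z = 0.5e-3),
                          n = list(r = 48L, z = 48L), T0 = 293.15) {
  dr <- extent$r / n$r; dz <- extent$z / n$z
  structure(list(
    temperature = matrix(T0, n$r, n$z),
    ablated = matrix(FALSE, n$r, n$z),
    deposited = matrix(0, n$r, n$z),  # cumulative source energy density, J/m^3
    grid = list(dr = dr, dz = dz, nr = n$r, nz = n$z,
                r = (seq_len(n$r) - 0.5) * dr, z = (seq_len(n$z) - 0.5) * dz),
    medium = medium, T0 = T0, time = 0),
    class = "thermal_field")
}

# Sparse conduction operator L such that dT/dt = alpha * L T (+ f/(rho cp)),
# with zero-flux faces on all boundaries and around ablated cells. The
# radial weights r_face/(r_i dr^2) make the discrete operator conservative
# under the ring-volume inner product.
conduction_operator <- function(field) {
  g <- field$grid
  nr <- g$nr; nz <- g$nz; dr <- g$dr; dz <- g$dz
  live <- !field$ablated
  ii <- list(); jj <- list(); xx <- list()
  put <- function(a, b, w_ab, w_ba) {
    k <- length(ii) + 1L
    ii[[k]] <<- c(a, a, b, b); jj[[k]] <<- c(b, a, a, b)
    xx[[k]] <<- c(w_ab, -w_ab, w_ba, -w_ba)
  }
  idx <- function(i, j) (j - 1L) * nr + i
  for (j in seq_len(nz)) {
    i <- which(live[-nr, j] & live[-1L, j])
    if (length(i) > 0) {
      rf <- i * dr
      put(idx(i, j), idx(i + 1L, j), rf / (g$r[i] * dr^2), rf / (g$r[i + 1L] * dr^2))
    }
  }
  for (j in seq_len(nz - 1L)) {
    i <- which(live[, j] & live[, j + 1L])
    if (length(i) > 0) {
      w <- rep(1 / dz^2, length(i))
      put(idx(i, j), idx(i, j + 1L), w, w)
    }
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(nr * nz, nr * nz))
}

# cached implicit stepper: factorizes (I - theta dt alpha L) once
heat_stepper <- function(field, dt, theta = 1) {
  m <- field$medium
  alpha <- m$k_cond / (m$rho * m$cp)
  op <- conduction_operator(field)
  n <- nrow(op)
  A <- Matrix::Diagonal(n) - (theta * dt * alpha) * op
  list(op = op, fac = Matrix::lu(A), dt = dt, theta = theta, alpha = alpha)
}

#' Advance the thermal field by one implicit conduction step
#'
#' @param field a `thermal_field`.
#' @param source volumetric power density f, W/m^3 (matrix matching the grid,
#'   or a scalar); applied over the step and accumulated into the per-cell
#'   deposited energy used by the ablation criterion.
#' @param dt time step, s (any dt is stable; accuracy is first order in dt
#'   for the default backward Euler, second order for theta = 0.5).
#' @param theta implicitness (1 backward Euler, 0.5 Crank-Nicolson).
#' @param stepper optionally a cached stepper from repeated calls (internal).
#' @return the updated `thermal_field`.
#' @export
step_heat <- function(field, source = 0, dt, theta = 1, stepper = NULL) {
  stopifnot_positive(dt = dt)
  m <- field$medium
  if (is.null(stepper) || stepper$dt != dt || stepper$theta != theta)
    stepper <- heat_stepper(field, dt, theta)
  Tvec <- as.vector(field$temperature)
  if (length(source) == 1L) source <- matrix(source, field$grid$nr, field$grid$nz)
  svec <- as.vector(source) / (m$rho * m$cp)
  svec[as.vector(field$ablated)] <- 0
  rhs <- Tvec + ((1 - theta) * dt * stepper$alpha) * as.vector(stepper$op %*% Tvec) +
    dt * svec
  Tnew <- as.vector(Matrix::solve(stepper$fac, rhs))
  field$temperature <- matrix(Tnew, field$grid$nr, field$grid$nz)
  src_dep <- source * dt
  src_dep[field$ablated] <- 0
  field$deposited <- field$deposited + src_dep
  field$time <- field$time + dt
  field
}

#' Total sensible enthalpy of the field relative to ambient
#'
#' @param field a `thermal_field`.
#' @return J, integral of rho*cp*(T - T0) over live cells.
#' @export
field_enthalpy <- function(field) {
  g <- field$grid; m <- field$medium
  vol <- 2 * pi * g$r * g$dr * g$dz     # ring volume, recycled over columns
  dT <- field$temperature - field$T0
  dT[field$ablated] <- 0
  m$rho * m$cp * sum(dT * vol)
}

#' Apply the melting-threshold ablation criterion
#'
#' A cell is ablated when (i) its temperature has reached the phase-change
#' temperature of the medium and (ii) the laser energy deposited into it
#' exceeds the volumetric thermal resistance of the material. Ablated cells
#' are removed from the conducting solid and never revert.
#'
#' @param field a `thermal_field`.
#' @param thermal_resistance volumetric ablation enthalpy threshold, J/m^3.
#' @return list(field = updated field, removed_volume = m^3,
#'   removed_cells = count).
#' @export
apply_ablation <- function(field, thermal_resistance) {
  stopifnot_positive(thermal_resistance = thermal_resistance)
  m <- field$medium
  newly <- !field$ablated &
    field$temperature >= m$melt_T &
    field$deposited > thermal_resistance
  g <- field$grid
  vol <- matrix(2 * pi * g$r * g$dr * g$dz, g$nr, g$nz)
  removed <- sum(vol[newly])
  field$ablated <- field$ablated | newly
  field$temperature[newly] <- field$T0
  field$deposited[newly] <- 0
  list(field = field, removed_volume = removed, removed_cells = sum(newly))
}

#' Mean surface irradiance of the diverging beam on the (cratered) surface
#'
#' Cone-divergence model: the beam radius grows from the fiber core radius
#' with half-angle asin(NA/n_water); the in-pulse mean irradiance is the
#' plateau-equivalent power Ep/fwhm spread over the illuminated disk at the
#' effective tip-to-surface distance (standoff + local crater depth).
#'
#' @param pulse a `laser_pulse`.
#' @param SD standoff distance, m (>= 0).
#' @param crater_depth local crater depth below the original surface, m.
#' @param prf_averaged if TRUE, the time-averaged power Ep*PRF spreads over
#'   the disk instead of the in-pulse average (alternative convention for
#'   comparing against ablation-threshold irradiances).
#' @param prf pulse repetition frequency, Hz (used when `prf_averaged`).
#' @return list(irradiance = W/m^2, beam_radius = m).
#' @export
surface_irradiance <- function(pulse, SD, crater_depth = 0,
                               prf_averaged = FALSE, prf = 20) {
  stopifnot_nonneg(SD = SD, crater_depth = crater_depth)
  n_water <- get_material("water", "optical")$n
  theta <- asin(pulse$numerical_aperture / n_water)
  dist <- SD + crater_depth
  w <- pulse$fiber_core_diameter / 2 + dist * tan(theta)
  P <- if (prf_averaged) pulse$Ep * prf else pulse$Ep / pulse$fwhm
  list(irradiance = P / (pi * w^2), beam_radius = w)
}

#' Multi-pulse photothermal crater evolution
#'
#' Per pulse: the calibrated absorbed fraction of the pulse energy is
#' deposited into the topmost live cell of each radial column inside the
#' diverging beam footprint, conduction is stepped implicitly through the
#' pulse, and the ablation criterion removes cells. Between pulses the
#' temperature relaxes exponentially toward ambient (time constant
#' `tau_cool`), representing conduction into the surrounding bulk stone and
#' fluid that a small insulated block cannot carry, while the deposited
#' ablation dose accumulates across pulses. Deeper layers receive a lower
#' irradiance (longer effective standoff, larger footprint) and therefore
#' need progressively more pulses per layer, until the per-pulse temperature
#' rise can no longer reach the ablation temperature: initially rapid crater
#' growth followed by saturation.
#'
#' @param SD standoff distance, m.
#' @param Ep pulse energy, J.
#' @param absorbed_fraction fraction of Ep absorbed by the stone surface, in
#'   [0, 1]; ~0.01 reproduces observed dusting craters. 0 yields all-zero
#'   records.
#' @param n_pulses number of pulses.
#' @param prf pulse repetition frequency, Hz.
#' @param medium stone thermal record (its `melt_T` is a calibration
#'   parameter for BegoStone, default 1450 K in the registry; see
#'   `melt_T_override`).
#' @param thermal_resistance volumetric ablation threshold, J/m^3
#'   (calibration parameter).
#' @param melt_T_override optional ablation temperature, K, replacing the
#'   registry value (default 550 K: BegoStone is gypsum-based and is removed
#'   by thermal decomposition well below silicate melting points; a
#'   calibration parameter together with `thermal_resistance`).
#' @param tau_cool inter-pulse relaxation time constant, s.
#' @param field optional pre-built `thermal_field` (domain/grid control).
#' @param pulse optional `laser_pulse` (defaults to the 0.2 J / 70 us
#'   dusting pulse).
#' @param n_steps_pulse implicit steps per pulse.
#' @return a `crater_history`: data.frame(pulse, volume_mm3, max_depth_mm,
#'   surface_area_mm2, mean_irradiance_W_mm2) with the final field as
#'   attribute "field". Crater volume and depth are nondecreasing.
#' @export
run_multi_pulse <- function(SD, Ep = 0.2, absorbed_fraction = 0.01,
                            n_pulses = 500L, prf = 20,
                            medium = get_material("begostone", "thermal"),
                            thermal_resistance = 8.5e9,
                            melt_T_override = 550,
                            tau_cool = 25e-3,
                            field = NULL, pulse = NULL,
                            n_steps_pulse = 4L) {
  if (absorbed_fraction < 0 || absorbed_fraction > 1)
    stop("absorbed_fraction must lie in [0, 1]", call. = FALSE)
  if (is.null(pulse)) pulse <- make_power_profile(Ep, 70e-6)
  if (!is.null(melt_T_override)) medium$melt_T <- melt_T_override
  if (is.null(field)) field <- thermal_field(medium = medium)
  field$medium <- medium
  g <- field$grid
  records <- data.frame(pulse = integer(0), volume_mm3 = numeric(0),
                        max_depth_mm = numeric(0), surface_area_mm2 = numeric(0),
                        mean_irradiance_W_mm2 = numeric(0))
  cum_volume <- 0
  pulse_dur <- pulse$fwhm
  dtp <- pulse_dur / n_steps_pulse
  stepper <- heat_stepper(field, dtp)
  relax <- exp(-max(0, 1 / prf - pulse_dur) / tau_cool)
  for (p in seq_len(n_pulses)) {
    surf_j <- apply(field$ablated, 1L, function(col) {
      k <- which(!col)
      if (length(k) == 0L) NA_integer_ else k[1L]
    })
    if (any(is.na(surf_j)) || any(field$ablated[, g$nz]))
      stop("crater reached the domain boundary; enlarge the domain", call. = FALSE)
    irr <- surface_irradiance(pulse, SD, crater_depth = (surf_j[1L] - 1L) * g$dz)
    w_beam <- irr$beam_radius

    if (absorbed_fraction > 0) {
      src <- matrix(0, g$nr, g$nz)
      in_beam <- which(g$r <= w_beam)
      area <- pi * w_beam^2
      flux <- absorbed_fraction * Ep / pulse_dur / area   # W/m^2 on the surface
      for (i in in_beam) src[i, surf_j[i]] <- flux / g$dz # into the top live cell
      for (s in seq_len(n_steps_pulse))
        field <- step_heat(field, src, dtp, stepper = stepper)
    }
    ab <- apply_ablation(field, thermal_resistance)
    field <- ab$field
    if (ab$removed_cells > 0L) stepper <- heat_stepper(field, dtp)
    cum_volume <- cum_volume + ab$removed_volume

    # inter-pulse relaxation toward ambient (bulk acting as heat sink)
    field$temperature <- field$T0 + (field$temperature - field$T0) * relax
    field$time <- field$time + 1 / prf

    depth_cells <- apply(field$ablated, 1L, function(col) sum(cumprod(col)))
    opened <- field$ablated[, 1L]
    records <- rbind(records, data.frame(
      pulse = p,
      volume_mm3 = cum_volume * 1e9,
      max_depth_mm = max(depth_cells) * g$dz * 1e3,
      surface_area_mm2 = sum(2 * pi * g$r[opened] * g$dr) * 1e6,
      mean_irradiance_W_mm2 = irr$irradiance / 1e6))
  }
  structure(records, class = c("crater_history", "data.frame"), field = field)
}

#' @method print crater_history
#' @export
print.crater_history <- function(x, ...) {
  last <- x[nrow(x), ]
  cat(sprintf("<crater_history> %d pulses: volume %.4g mm^3, max depth %.3g mm\n",
              nrow(x), last$volume_mm3, last$max_depth_mm))
  invisible(x)
}
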