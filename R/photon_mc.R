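# Monte Carlo photon transport through water / vapor bubble / stone with
# per-segment dynamic geometry: deposition maps, transmission fractions and
# the fluid/solid energy partition.

#' Beer-Lambert transmission along a straight path
#'
#' @param path_length m, >= 0.
#' @param mu_a absorption coefficient, m^-1, >= 0.
#' @return exp(-mu_a * path_length).
#' @export
beer_lambert_transmission <- function(path_length, mu_a) {
  stopifnot_nonneg(path_length = path_length, mu_a = mu_a)
  exp(-mu_a * path_length)
}

#' Build an axisymmetric media map for photon transport
#'
#' The transport frame has z = 0 at the fiber face, increasing toward the
#' stone surface at z = `SD` (the target plane where transmitted energy is
#' tallied). An optional vapor mask (from a [make_bubble_geometry_sequence()]
#' segment, whose axial convention has z = 0 at the stone) is flipped into
#' this frame.
#'
#' @param SD standoff distance fiber tip to stone, m.
#' @param dr,dz voxel sizes, m.
#' @param rmax radial extent, m.
#' @param vapor_mask optional logical matrix (nr x nz, geometry-frame
#'   columns) marking vapor voxels.
#' @param vapor_radius optional radius of a full-length cylindrical vapor
#'   channel, m (alternative to `vapor_mask`; the Moses-limit geometry).
#' @param optics per-label optical records (label 1 = water, 2 = vapor).
#' @return a `media_map`: integer label matrix (1 = water, 2 = vapor), voxel
#'   sizes, target plane and per-label optical records.
#' @export
make_media_map <- function(SD, dr = 10e-6, dz = 10e-6, rmax = 1e-3,
                           vapor_mask = NULL, vapor_radius = NULL,
                           optics = list(water = get_material("water", "optical"),
                                         vapor = get_material("vapor", "optical"))) {
  stopifnot_positive(SD = SD, dr = dr, dz = dz, rmax = rmax)
  nz <- ceiling(SD / dz)
  nr <- ceiling(rmax / dr)
  labels <- matrix(1L, nr, nz)
  if (!is.null(vapor_mask)) {
    gm_nr <- nrow(vapor_mask); gm_nz <- ncol(vapor_mask)
    # geometry frame: column j covers z_geom in ((j-1)dz, j dz], z_geom from stone;
    # transport frame column k corresponds to geometry column nz - k + 1
    for (k in seq_len(nz)) {
      jg <- gm_nz - k + 1L
      if (jg < 1L || jg > gm_nz) next
      occ <- which(vapor_mask[, jg])
      occ <- occ[occ <= nr]
      if (length(occ)) labels[occ, k] <- 2L
    }
  }
  if (!is.null(vapor_radius)) {
    labels[(seq_len(nr) - 0.5) * dr <= vapor_radius, ] <- 2L
  }
  structure(list(labels = labels, dr = dr, dz = dz, SD = SD,
                 z_target = nz * dz, optics = optics,
                 label_names = c("water", "vapor")),
            class = "media_map")
}

#' Trace one pulse segment through a media map
#'
#' Launches `n_photons` packets from the fiber face (uniform over the core,
#' uniform in solid angle within the NA cone in water) carrying
#' `pulse_segment_energy` in total, with continuous absorption weight
#' deposition along paths and Henyey-Greenstein scattering where mu_s > 0.
#' Transport ends at the target plane (transmitted), the domain boundary
#' (escaped) or by terminal deposition of negligible residual weight.
#'
#' @param pulse_segment_energy J.
#' @param media a `media_map`.
#' @param n_photons packet count (>= 1000 for meaningful tallies).
#' @param seed RNG seed (required: runs are reproducible by seed).
#' @param fiber_core_diameter m.
#' @param numerical_aperture dimensionless.
#' @param collimated launch all packets axially (for analytic comparisons).
#' @param step transport step, m (default min(dr, dz)).
#' @return a `deposition_map`: absorbed energy per voxel (J), transmitted,
#'   escaped, launched; absorbed + transmitted + escaped = launched to 1e-6
#'   relative (asserted).
#' @export
trace_segment <- function(pulse_segment_energy, media, n_photons = 1e4, seed,
                          fiber_core_diameter = 365e-6, numerical_aperture = 0.26,
                          collimated = FALSE, step = NULL) {
  stopifnot(inherits(media, "media_map"))
  stopifnot_nonneg(pulse_segment_energy = pulse_segment_energy)
  if (n_photons < 1e3) stop("n_photons must be at least 1000", call. = FALSE)
  if (missing(seed)) stop("an RNG seed is required for reproducibility", call. = FALSE)
  labs <- sort(unique(as.vector(media$labels)))
  if (any(labs < 1L) || any(labs > length(media$optics)))
    stop("media map contains unregistered voxel labels", call. = FALSE)
  if (is.null(step)) step <- min(media$dr, media$dz)
  mua <- vapply(media$optics, function(o) o$mu_a_si, numeric(1))
  mus <- vapply(media$optics, function(o) o$mu_s_si, numeric(1))
  gg <- vapply(media$optics, function(o) o$g, numeric(1))
  n_water <- media$optics[[1]]$n
  sin_max <- if (collimated) 0 else numerical_aperture / n_water
  res <- mc_trace_cpp(media$labels, media$dr, media$dz, mua, mus, gg,
                      media$z_target, fiber_core_diameter / 2, sin_max,
                      as.integer(n_photons), pulse_segment_energy, step,
                      as.integer(seed), collimated)
  closure <- abs(res$absorbed_total + res$transmitted + res$escaped - res$launched)
  if (res$launched > 0 && closure / res$launched > 1e-6)
    stop("energy conservation violated in photon transport", call. = FALSE)
  structure(list(absorbed = res$absorbed, absorbed_total = res$absorbed_total,
                 transmitted = res$transmitted, escaped = res$escaped,
                 launched = res$launched,
                 grid = list(dr = media$dr, dz = media$dz)),
            class = "deposition_map")
}

#' @method print deposition_map
#' @export
print.deposition_map <- function(x, ...) {
  cat(sprintf("<deposition_map> launched %.4g J: absorbed %.4g, transmitted %.4g, escaped %.4g\n",
              x$launched, x$absorbed_total, x$transmitted, x$escaped))
  invisible(x)
}

#' Dynamic per-segment Monte Carlo energy partition
#'
#' Runs [trace_segment()] for each pulse segment against the corresponding
#' vapor-bubble geometry frame and reduces the per-segment deposition maps
#' to fluid / solid / escaped fractions weighted by the segment energies.
#'
#' @param pulse a `laser_pulse`.
#' @param geometry a `bubble_geometry_sequence` covering the standoff gap.
#' @param n_photons_per_segment packets per segment.
#' @param seed RNG seed; per-segment seeds are derived deterministically.
#' @param rmax radial extent of the transport grid, m.
#' @return an `energy_budget`: fraction_fluid, fraction_solid,
#'   fraction_escaped (summing to 1 within 1e-6) and a per-segment
#'   data.frame.
#' @export
run_dynamic_simulation <- function(pulse, geometry, n_photons_per_segment = 2e4,
                                   seed = 1L, rmax = 1.0e-3) {
  stopifnot(inherits(pulse, "laser_pulse"), inherits(geometry, "bubble_geometry_sequence"))
  n_seg <- length(geometry$masks) - 1L
  E_seg <- segment_energies(pulse, n_seg)
  if (length(E_seg) != n_seg)
    stop("pulse segmentation does not match the geometry sequence", call. = FALSE)
  per <- data.frame(segment = seq_len(n_seg), energy = E_seg,
                    fluid = NA_real_, solid = NA_real_, escaped = NA_real_)
  tot <- c(fluid = 0, solid = 0, escaped = 0)
  for (s in seq_len(n_seg)) {
    media <- make_media_map(geometry$SD, dr = geometry$grid_spec$dr,
                            dz = geometry$grid_spec$dz, rmax = rmax,
                            vapor_mask = geometry$masks[[s + 1L]])
    dm <- trace_segment(E_seg[s], media, n_photons = n_photons_per_segment,
                        seed = derive_seed(seed, "mc") + s)
    per$fluid[s] <- dm$absorbed_total
    per$solid[s] <- dm$transmitted
    per$escaped[s] <- dm$escaped
    tot <- tot + c(dm$absorbed_total, dm$transmitted, dm$escaped)
  }
  tot <- tot / sum(E_seg)
  structure(list(fraction_fluid = tot[["fluid"]], fraction_solid = tot[["solid"]],
                 fraction_escaped = tot[["escaped"]], per_segment = per,
                 Ep = pulse$Ep),
            class = "energy_budget")
}

#' @method print energy_budget
#' @export
print.energy_budget <- function(x, ...) {
  cat(sprintf("<energy_budget> fluid %.1f%%, solid %.1f%%, escaped %.1f%% of Ep = %.3g J\n",
              100 * x$fraction_fluid, 100 * x$fraction_solid,
              100 * x$fraction_escaped, x$Ep))
  invisible(x)
}

#' Transmission through a fully developed vapor channel (Moses limit)
#'
#' Builds a cylindrical vapor channel spanning the fiber face to the target
#' plane at standoff `SD` (water outside) and reports the percentage of
#' launched energy reaching the target.
#'
#' @param SD standoff distance, m.
#' @param channel_radius m; default encloses the NA beam envelope at the
#'   target (core radius + SD tan(theta_NA)) with a 10% margin.
#' @param n_photons packets.
#' @param seed RNG seed.
#' @return list(transmission_percent, deposition = `deposition_map`).
#' @export
vapor_channel_transmission <- function(SD = 0.5e-3, channel_radius = NULL,
                                       n_photons = 1e5, seed = 1L) {
  n_water <- get_material("water", "optical")$n
  theta <- asin(0.26 / n_water)
  if (is.null(channel_radius))
    channel_radius <- 1.1 * (365e-6 / 2 + SD * tan(theta))
  media <- make_media_map(SD, vapor_radius = channel_radius,
                          rmax = max(1e-3, 2 * channel_radius))
  dm <- trace_segment(1.0, media, n_photons = n_photons, seed = seed)
  list(transmission_percent = 100 * dm$transmitted / dm$launched, deposition = dm)
}
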