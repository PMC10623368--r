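# Synthetic bubble kinematics: axisymmetric geometry sequences for the
# photon transport, equivalent-radius-time curves for the energetics
# analysis, and silhouette images standing in for shadowgraph frames.
#
# Coordinates: axisymmetric (r, z) with z = 0 at the solid boundary and z
# increasing toward the fiber tip at z = SD; cell-centered voxels.

#' Generate an axisymmetric vapor-bubble geometry sequence
#'
#' Emulates the pear-shaped vapor bubble of long-pulse lithotripsy growing
#' from the fiber tip toward the stone: per segment s the vapor region is the
#' solid of revolution r <= B*sqrt(zeta*(2*zc(s) - zeta)) with zeta the
#' distance below the fiber tip, zc(s) growing linearly so the bubble apex
#' reaches the stone surface at segment `n_contact`, and the width scale B
#' fixed so the final (clipped) volume equals the volume of a sphere of
#' radius `Re_max`. Masks are nested (monotone growth) and simply connected
#' by construction; segment 0 is empty (pre-inception).
#'
#' @param SD standoff distance fiber tip to stone surface, m (> 0).
#' @param Re_max maximum volume-equivalent bubble radius, m.
#' @param n_seg number of segments (default 30, i.e. 5 us segments of a
#'   150 us pulse).
#' @param n_contact segment at which the bubble apex reaches the stone
#'   (default 5, the observed value at SD = 0.5 mm).
#' @param grid_spec list(dr, dz) voxel sizes, m; radial extent is sized
#'   automatically to contain the final bubble.
#' @param segment_duration s, duration of one segment.
#' @return a `bubble_geometry_sequence`: list of logical masks (nr x nz, rows
#'   = radial cells at r_i = (i-1/2) dr, cols = axial cells spanning [0, SD]),
#'   plus `grid_spec`, `Re_per_segment` (volume-equivalent radius per
#'   segment, by voxel summation), `SD`, `segment_duration`.
#' @export
make_bubble_geometry_sequence <- function(SD, Re_max, n_seg = 30L, n_contact = 5L,
                                          grid_spec = list(dr = 10e-6, dz = 10e-6),
                                          segment_duration = 5e-6) {
  stopifnot_positive(SD = SD, Re_max = Re_max)
  dr <- grid_spec$dr; dz <- grid_spec$dz
  if (SD / dz < 8) stop("grid too coarse: fewer than 8 axial cells across the standoff gap", call. = FALSE)

  zc <- SD * seq_len(n_seg) / (2 * n_contact)
  # width scale grows linearly with segment (slender pear early, spreading
  # late); its final value is set by the target final volume of the clipped
  # solid of revolution
  zcn <- zc[n_seg]
  L <- min(2 * zcn, SD)
  V_target <- 4 / 3 * pi * Re_max^3
  B_final <- sqrt(V_target / (pi * (zcn * L^2 - L^3 / 3)))
  B_seg <- B_final * seq_len(n_seg) / n_seg

  zeta_star <- min(zcn, SD)  # widest point of the final clipped region
  r_final_max <- B_final * sqrt(zeta_star * (2 * zcn - zeta_star))
  nr <- ceiling(1.05 * r_final_max / dr)
  nz <- ceiling(SD / dz)
  r_cells <- (seq_len(nr) - 0.5) * dr
  z_cells <- (seq_len(nz) - 0.5) * dz
  zeta <- SD - z_cells  # depth below fiber tip

  masks <- vector("list", n_seg + 1L)
  masks[[1L]] <- matrix(FALSE, nr, nz)  # segment 0: pre-inception
  Re_seg <- numeric(n_seg + 1L)
  for (s in seq_len(n_seg)) {
    rad <- B_seg[s] * sqrt(pmax(0, zeta * (2 * zc[s] - zeta)))
    rad[zeta > 2 * zc[s]] <- 0
    masks[[s + 1L]] <- outer(r_cells, rad, FUN = `<=`)
    V <- sum(t(masks[[s + 1L]]) %*% (2 * pi * r_cells) * dr * dz)
    Re_seg[s + 1L] <- (3 * V / (4 * pi))^(1 / 3)
  }
  structure(list(masks = masks, grid_spec = list(dr = dr, dz = dz, nr = nr, nz = nz),
                 Re_per_segment = Re_seg, SD = SD, n_contact = n_contact,
                 segment_duration = segment_duration,
                 apex_depth = pmin(2 * zc, SD), width_scale = B_seg),
            class = "bubble_geometry_sequence")
}

#' @method print bubble_geometry_sequence
#' @export
print.bubble_geometry_sequence <- function(x, ...) {
  cat(sprintf("<bubble_geometry_sequence> %d segments of %.3g us, SD = %.3g mm\n",
              length(x$masks) - 1L, x$segment_duration * 1e6, x$SD * 1e3))
  cat(sprintf("  grid %d x %d (dr = %.3g um, dz = %.3g um); final Re = %.3g mm; apex contact at segment %d\n",
              x$grid_spec$nr, x$grid_spec$nz, x$grid_spec$dr * 1e6, x$grid_spec$dz * 1e6,
              x$Re_per_segment[length(x$Re_per_segment)] * 1e3, x$n_contact))
  invisible(x)
}

#' Generate a synthetic equivalent-radius-time curve
#'
#' Builds a labeled radius history with the canonical event sequence of a
#' lithotripsy bubble: inception, growth to the maximum at `t_max`, primary
#' collapse at t1 = k1_target * 2 * Tc(Re_max) (so the downstream
#' prolongation-factor estimate recovers `k1_target`), rebound to
#' rebound_fraction^(1/3) * Re_max (volume-fraction convention), and
#' secondary collapse. Growth and collapse limbs use the Rayleigh-like shape
#' R proportional to (u(2-u))^(1/3).
#'
#' @param Re_max maximum equivalent radius, m.
#' @param t_max time of maximum, s; must precede the primary collapse implied
#'   by `k1_target`.
#' @param k1_target prolongation factor t1/(2 Tc), >= growth allows.
#' @param rebound_fraction rebound volume fraction EB1/EB in (0, 1).
#' @param dt sample spacing, s.
#' @param fluid ambient fluid record (for Tc).
#' @return a `radius_time_series`: list(times, Re, events, fluid).
#' @export
make_radius_time <- function(Re_max, t_max, k1_target, rebound_fraction,
                             dt = 0.1e-6, fluid = ambient_water()) {
  stopifnot_positive(Re_max = Re_max, t_max = t_max, dt = dt)
  if (k1_target < 0.5) stop("k1_target must be >= 0.5", call. = FALSE)
  if (rebound_fraction <= 0 || rebound_fraction >= 1)
    stop("rebound_fraction must lie in (0, 1)", call. = FALSE)
  Tc <- rayleigh_collapse_time(Re_max, fluid)
  t1 <- k1_target * 2 * Tc
  if (t1 <= t_max)
    stop(sprintf(paste("primary collapse t1 = k1*2*Tc = %.3g s would precede the radius",
                       "maximum t_max = %.3g s; increase k1_target or reduce t_max"),
                 t1, t_max), call. = FALSE)
  if (dt > (t1 - t_max) / 20)
    stop("dt too coarse to resolve the collapse limb; need dt <= (t1 - t_max)/20", call. = FALSE)

  R2 <- rebound_fraction^(1 / 3) * Re_max
  tau2 <- rayleigh_collapse_time(R2, fluid)
  t2 <- t1 + tau2       # rebound maximum
  t3 <- t1 + 2 * tau2   # secondary collapse
  times <- seq(0, t3, by = dt)
  limb <- function(u) (pmax(0, u * (2 - u)))^(1 / 3)
  Re <- numeric(length(times))
  g <- times <= t_max
  Re[g] <- Re_max * limb(times[g] / t_max)
  cidx <- times > t_max & times <= t1
  Re[cidx] <- Re_max * limb((t1 - times[cidx]) / (t1 - t_max))
  ridx <- times > t1
  Re[ridx] <- R2 * limb(1 - abs(times[ridx] - t2) / tau2)

  events <- c(inception = 0, maximum = t_max, primary_collapse = t1,
              rebound_max = t2, secondary_collapse = t3)
  structure(list(times = times, Re = Re, events = events, fluid = fluid),
            class = "radius_time_series")
}

#' @method print radius_time_series
#' @export
print.radius_time_series <- function(x, ...) {
  cat(sprintf("<radius_time_series> %d samples to %.3g us; Re_max = %.3g mm\n",
              length(x$times), max(x$times) * 1e6, max(x$Re) * 1e3))
  ev <- paste(sprintf("%s @ %.1f us", names(x$events), x$events * 1e6), collapse = ", ")
  cat(" ", ev, "\n")
  invisible(x)
}

#' @method plot radius_time_series
#' @export
plot.radius_time_series <- function(x, ...) {
  graphics::plot(x$times * 1e6, x$Re * 1e3, type = "l", xlab = "time (us)",
                 ylab = "equivalent radius (mm)", ...)
  graphics::abline(v = x$events * 1e6, lty = 3, col = "grey50")
  invisible(x)
}

#' Generate a synthetic silhouette image of an axisymmetric region
#'
#' Renders the projected silhouette of a solid of revolution given its radial
#' profile, optionally Gaussian-blurred and corrupted with pixel noise, as a
#' stand-in for a backlit shadowgraph frame.
#'
#' @param profile either a function r(z) in metres returning the radial
#'   extent at axial position z in [0, z_extent], or a
#'   `bubble_geometry_sequence` (with `segment` selecting the frame).
#' @param z_extent axial extent covered by `profile`, m (ignored for
#'   geometry sequences).
#' @param pixel_pitch m per pixel; must resolve the region by >= 20 px across.
#' @param blur Gaussian blur standard deviation in pixels (0 = none).
#' @param noise_sd additive pixel noise standard deviation (intensity units).
#' @param seed RNG seed for the noise (deterministic given seed).
#' @param segment segment index when `profile` is a geometry sequence.
#' @return a `silhouette_image`: list(intensity = matrix in [0,1] with rows =
#'   axial pixels and cols = lateral pixels, pixel_pitch, threshold = 0.5,
#'   axis_col).
#' @export
make_silhouette <- function(profile, z_extent = NULL, pixel_pitch = 10e-6,
                            blur = 0, noise_sd = 0, seed = 1L, segment = NULL) {
  if (inherits(profile, "bubble_geometry_sequence")) {
    geom <- profile
    if (is.null(segment)) stop("supply 'segment' for a geometry sequence", call. = FALSE)
    mask <- geom$masks[[segment + 1L]]
    dr <- geom$grid_spec$dr; dz <- geom$grid_spec$dz
    z_extent <- geom$grid_spec$nz * dz
    rad_at <- function(z) {
      j <- pmin(geom$grid_spec$nz, pmax(1L, ceiling(z / dz)))
      vapply(j, function(jj) {
        occ <- which(mask[, jj])
        if (length(occ) == 0) 0 else max(occ) * dr
      }, numeric(1))
    }
  } else {
    stopifnot(is.function(profile), !is.null(z_extent))
    rad_at <- profile
  }
  stopifnot_positive(pixel_pitch = pixel_pitch)
  zs <- seq(pixel_pitch / 2, z_extent, by = pixel_pitch)
  rmax <- max(vapply(zs, function(z) rad_at(z), numeric(1)))
  if (rmax <= 0) stop("profile is empty", call. = FALSE)
  if (2 * rmax / pixel_pitch < 20)
    stop("pixel_pitch too coarse: fewer than 20 px across the region", call. = FALSE)

  half_px <- ceiling(rmax / pixel_pitch) + 4L + 3L * ceiling(blur)
  ncol_img <- 2L * half_px + 1L
  axis_col <- half_px + 1L
  xs <- (seq_len(ncol_img) - axis_col) * pixel_pitch
  img <- matrix(0, nrow = length(zs), ncol = ncol_img)
  for (i in seq_along(zs)) {
    r <- rad_at(zs[i])
    img[i, abs(xs) <= r] <- 1
  }
  if (blur > 0) img <- gaussian_blur(img, blur)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    img <- img + matrix(rnorm(length(img), sd = noise_sd), nrow = nrow(img))
  }
  structure(list(intensity = img, pixel_pitch = pixel_pitch, threshold = 0.5,
                 axis_col = axis_col),
            class = "silhouette_image")
}

# separable Gaussian blur with reflective edges
gaussian_blur <- function(img, sd_px) {
  half <- max(1L, ceiling(3 * sd_px))
  k <- exp(-((-half):half)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    idx <- seq_len(n)
    out <- numeric(n)
    for (o in (-half):half) {
      j <- pmin(n, pmax(1L, idx + o))
      out <- out + k[o + half + 1L] * v[j]
    }
    out
  }
  img <- apply(img, 2L, smooth_vec)
  t(apply(img, 1L, smooth_vec))
}
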