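# Material property registry: optical, thermal, elastic and ambient-fluid
# records for the media involved in laser lithotripsy (water, vapor,
# BegoStone phantom, quartz, photoelastic polymer).

.lithocav_env <- new.env(parent = emptyenv())

#' Load a material registry
#'
#' Reads a JSON registry of material property records and installs it as the
#' active registry for [get_material()]. Optical absorption and scattering
#' coefficients are given in the registry file in mm^-1 (the conventional
#' unit at 2080 nm) and converted once to SI (m^-1) alongside.
#'
#' Every record is validated against its type invariants at load time:
#' non-negative optical coefficients, anisotropy in [-1, 1], refractive index
#' >= 1, strictly positive thermal properties, positive-definite elasticity
#' (c_L > c_T * sqrt(4/3)), and p_stat > p_v > 0 for ambient fluids.
#'
#' @param path path to a JSON registry; default is the registry shipped with
#'   the package (fused-quartz and published hard-BegoStone elastic constants
#'   stand in for unavailable measured values).
#' @return invisibly, the validated registry list.
#' @export
load_materials <- function(path = system.file("extdata", "materials.json",
                                              package = "lithocav")) {
  reg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  reg[["_comment"]] <- NULL
  for (kind in names(reg)) {
    for (nm in names(reg[[kind]])) {
      rec <- reg[[kind]][[nm]]
      rec$name <- nm
      if (kind == "optical") {
        rec$mu_a_si <- rec$mu_a * 1000  # mm^-1 -> m^-1
        rec$mu_s_si <- rec$mu_s * 1000
      }
      validate_material(rec, kind)
      reg[[kind]][[nm]] <- rec
    }
  }
  assign("materials", reg, envir = .lithocav_env)
  invisible(reg)
}

validate_material <- function(rec, kind) {
  bad <- function(msg) stop(sprintf("material '%s' (%s): %s", rec$name, kind, msg),
                            call. = FALSE)
  switch(kind,
    optical = {
      if (rec$mu_a < 0 || rec$mu_s < 0) bad("mu_a and mu_s must be >= 0")
      if (rec$g < -1 || rec$g > 1) bad("anisotropy g must lie in [-1, 1]")
      if (rec$n < 1) bad("refractive index must be >= 1")
    },
    thermal = {
      if (any(c(rec$rho, rec$cp, rec$k_cond, rec$melt_T, rec$latent_heat_vap) <= 0))
        bad("all thermal properties must be strictly positive")
      if (rec$melt_T <= 293.15) bad("melting/phase-change temperature must exceed ambient")
    },
    elastic = {
      if (any(c(rec$rho, rec$c_L, rec$c_T) <= 0)) bad("all elastic properties must be positive")
      if (rec$c_L <= rec$c_T * sqrt(4 / 3))
        bad("c_L must exceed c_T*sqrt(4/3) for positive-definite elasticity")
    },
    fluid = {
      if (any(c(rec$rho, rec$c, rec$p_stat, rec$p_v, rec$T0) <= 0))
        bad("all fluid properties must be positive")
      if (rec$p_stat <= rec$p_v) bad("p_stat must exceed p_v")
    },
    bad("unknown material kind")
  )
  invisible(TRUE)
}

material_registry <- function() {
  if (!exists("materials", envir = .lithocav_env)) load_materials()
  get("materials", envir = .lithocav_env)
}

#' Look up a material property record
#'
#' @param name material name, e.g. "water", "vapor", "begostone", "quartz".
#' @param kind one of "optical", "thermal", "elastic", "fluid".
#' @return a named list of properties. Optical records carry `mu_a`, `mu_s`
#'   in mm^-1 (registry convention) plus `mu_a_si`, `mu_s_si` in m^-1,
#'   anisotropy `g` and refractive index `n`. Thermal records carry `rho`
#'   (kg/m^3), `cp` (J/kg/K), `k_cond` (W/m/K), `melt_T` (K),
#'   `latent_heat_vap` (J/kg). Elastic records carry `rho`, `c_L`, `c_T`
#'   (m/s). Fluid records carry `rho`, sound speed `c`, `p_stat`, `p_v` (Pa)
#'   and ambient temperature `T0` (K).
#' @examples
#' get_material("water", "optical")$mu_a   # 2.42 mm^-1 at 2080 nm
#' get_material("vapor", "optical")$mu_a   # 0.001 mm^-1
#' @export
get_material <- function(name, kind = c("optical", "thermal", "elastic", "fluid")) {
  reg <- material_registry()
  if (length(kind) != 1L || !kind %in% names(reg)) {
    stop(sprintf("unknown material kind %s; available kinds: %s",
                 paste(deparse(substitute(kind))),
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  }
  tab <- reg[[kind]]
  if (!name %in% names(tab)) {
    stop(sprintf("unknown %s material '%s'; available: %s",
                 kind, name, paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  tab[[name]]
}

#' Ambient water at 1 atm, 20 degrees C
#'
#' Convenience accessor for the default ambient fluid; its driving pressure
#' difference p_stat - p_v = 98986 Pa enters the Rayleigh collapse time and
#' bubble potential energy.
#' @return the "water" fluid record.
#' @export
ambient_water <- function() get_material("water", "fluid")
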