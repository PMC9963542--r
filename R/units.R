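#' Build a physical-to-lattice unit system
#'
#' The lattice Boltzmann solver works in reduced units in which the lattice
#' spacing and the time step are both 1.  Physical quantities are mapped onto
#' the lattice by conversion factors: the base factors for length, density and
#' kinematic viscosity are the ratios of the physical value to its lattice
#' counterpart, and all derived factors follow by dimensional analysis:
#' \deqn{C.F._t = C.F._l^2 / C.F._\nu, \quad
#'       C.F._u = C.F._l / C.F._t, \quad
#'       C.F._F = C.F._u^2 \, C.F._l^2 \, C.F._\rho.}
#' Matching the Reynolds number between the two domains is then automatic for
#' any flow configured consistently through the ledger.
#'
#' @param channel_width_phys physical channel width in metres.
#' @param lattice_width channel width in lattice nodes.
#' @param rho_phys fluid density in kg/m^3.
#' @param rho_lbm lattice fluid density (usually 1).
#' @param nu_phys kinematic viscosity in m^2/s.
#' @param nu_lbm lattice kinematic viscosity (sets the relaxation time via
#'   \code{\link{tauFromViscosity}}).
#'
#' @return An object of class \code{unit_system}: a list of conversion factors
#'   \code{cf_length} (m), \code{cf_density} (kg/m^3), \code{cf_viscosity}
#'   (m^2/s), \code{cf_time} (s), \code{cf_velocity} (m/s), \code{cf_force}
#'   (N) and \code{cf_energy_density} (J/m^3, pressure-like, defined as
#'   \code{cf_force / cf_length^2}).
#' @examples
#' us <- buildUnitSystem(160e-6, 80, 1027, 1, 1e-6, 0.0167)
#' us$cf_length   # 2 um per lattice spacing
#' @export
buildUnitSystem <- function(channel_width_phys, lattice_width,
                            rho_phys, rho_lbm, nu_phys, nu_lbm) {
  args <- list(channel_width_phys = channel_width_phys,
               lattice_width = lattice_width, rho_phys = rho_phys,
               rho_lbm = rho_lbm, nu_phys = nu_phys, nu_lbm = nu_lbm)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      .stop_invalid(nm, "must be a single positive finite number")
  }
  cf_l <- channel_width_phys / lattice_width
  cf_rho <- rho_phys / rho_lbm
  cf_nu <- nu_phys / nu_lbm
  cf_t <- cf_l^2 / cf_nu
  cf_u <- cf_l / cf_t
  cf_f <- cf_u^2 * cf_l^2 * cf_rho
  us <- list(cf_length = cf_l, cf_density = cf_rho, cf_viscosity = cf_nu,
             cf_time = cf_t, cf_velocity = cf_u, cf_force = cf_f,
             cf_energy_density = cf_f / cf_l^2,
             channel_width_phys = channel_width_phys,
             lattice_width = lattice_width,
             nu_lbm = nu_lbm, rho_lbm = rho_lbm)
  class(us) <- "unit_system"
  us
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  length    : %.6g m per lattice spacing\n", x$cf_length))
  cat(sprintf("  time      : %.6g s per lattice step\n", x$cf_time))
  cat(sprintf("  density   : %.6g kg/m^3 per lattice unit\n", x$cf_density))
  cat(sprintf("  viscosity : %.6g m^2/s per lattice unit\n", x$cf_viscosity))
  cat(sprintf("  velocity  : %.6g m/s per lattice unit\n", x$cf_velocity))
  cat(sprintf("  force     : %.6g N per lattice unit\n", x$cf_force))
  invisible(x)
}

.unit_factors <- function(units) {
  c(length = units$cf_length, time = units$cf_time,
    density = units$cf_density, viscosity = units$cf_viscosity,
    velocity = units$cf_velocity, force = units$cf_force,
    energy_density = units$cf_energy_density)
}

#' Convert quantities between the physical and lattice domains
#'
#' Multiplies (lattice direction) or divides (physical to lattice) by the
#' conversion factor of the named quantity kind, elementwise for fields.
#'
#' @param value scalar or numeric array.
#' @param quantity one of \code{"length"}, \code{"time"}, \code{"density"},
#'   \code{"viscosity"}, \code{"velocity"}, \code{"force"},
#'   \code{"energy_density"}.
#' @param direction \code{"to_lattice"} or \code{"to_physical"}.
#' @param units a \code{\link{buildUnitSystem}} ledger.
#' @return the converted value, same shape as \code{value}.
#' @export
convertUnits <- function(value, quantity, direction = c("to_lattice", "to_physical"),
                         units) {
  direction <- match.arg(direction)
  facs <- .unit_factors(units)
  if (!quantity %in% names(facs))
    .stop_invalid("quantity", sprintf(
      "unknown quantity kind '%s'; supported kinds: %s",
      quantity, paste(names(facs), collapse = ", ")))
  if (direction == "to_lattice") value / facs[[quantity]]
  else value * facs[[quantity]]
}

#' Reynolds number
#'
#' \code{Re = u L / nu}.  For any consistent unit ledger the value is identical
#' whether computed from physical or lattice quantities.
#'
#' @param u_char characteristic velocity.
#' @param length_char characteristic length (> 0).
#' @param nu kinematic viscosity (> 0).
#' @return dimensionless Reynolds number.
#' @export
reynoldsNumber <- function(u_char, length_char, nu) {
  if (!is.numeric(length_char) || length_char <= 0)
    .stop_invalid("length_char", "must be > 0")
  if (!is.numeric(nu) || nu == 0)
    .stop_invalid("nu", "division by zero viscosity")
  if (nu < 0) .stop_invalid("nu", "must be > 0")
  u_char * length_char / nu
}

#' Serialize a unit ledger to a plain named list (for config echoes)
#' @param units a \code{unit_system}.
#' @return a named list of numeric conversion factors.
#' @export
unitLedger <- function(units) {
  as.list(.unit_factors(units))
}
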