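#' Acoustic contrast factor
#'
#' \deqn{\Phi(\beta, \rho) = \frac{5\rho_p - 2\rho_f}{2\rho_p + \rho_f}
#'   - \frac{\beta_p}{\beta_f}}
#' Particles with positive contrast migrate to the pressure nodes of a
#' standing wave, negative-contrast particles to the antinodes.
#'
#' @param beta_p particle compressibility (1/Pa).
#' @param beta_f fluid compressibility (1/Pa).
#' @param rho_p particle density (kg/m^3).
#' @param rho_f fluid density (kg/m^3).
#' @return dimensionless contrast factor.
#' @export
contrastFactor <- function(beta_p, beta_f, rho_p, rho_f) {
  for (nm in c("beta_p", "beta_f", "rho_p", "rho_f")) {
    v <- get(nm)
    if (!is.numeric(v) || any(v <= 0)) .stop_invalid(nm, "must be > 0")
  }
  (5 * rho_p - 2 * rho_f) / (2 * rho_p + rho_f) - beta_p / beta_f
}

#' SSAW acoustic field configuration
#'
#' The acoustic energy density can be given directly or as a drive voltage
#' with the device's proportionality constant \eqn{E_{ac} = a V^2} (exactly
#' one of the two forms must be supplied).  \code{phase_offset} shifts the
#' standing-wave pattern along the channel width; the sign convention of the
#' force is fixed so that for positive contrast the stable pressure nodes sit
#' at \eqn{y = \mathrm{phase\_offset} + k\,\lambda/2}.
#'
#' @param wavelength SSAW wavelength in metres.
#' @param energy_density acoustic energy density in J/m^3, or \code{NULL} if
#'   \code{voltage} and \code{a} are given.
#' @param voltage drive voltage (V); requires \code{a}.
#' @param a proportionality constant (J/m^3/V^2).
#' @param phase_offset shift of the node pattern in metres.
#' @param active logical; an inactive field exerts zero force.
#' @param fluid_density fluid density (kg/m^3).
#' @param fluid_compressibility fluid compressibility (1/Pa); the default is
#'   the standard value for water.
#' @return an \code{acoustic_config} list.
#' @export
acousticConfig <- function(wavelength, energy_density = NULL,
                           voltage = NULL, a = NULL,
                           phase_offset = wavelength / 4, active = TRUE,
                           fluid_density = 1027,
                           fluid_compressibility = 4.5e-10) {
  if (!is.numeric(wavelength) || wavelength <= 0)
    .stop_invalid("wavelength", "must be > 0")
  has_e <- !is.null(energy_density)
  has_v <- !is.null(voltage) || !is.null(a)
  if (has_e && has_v)
    .stop_config("supply exactly one of energy_density or (voltage, a)")
  if (!has_e) {
    if (is.null(voltage) || is.null(a))
      .stop_config("supply exactly one of energy_density or (voltage, a)")
    energy_density <- energyDensity(voltage, a)
  }
  if (energy_density < 0)
    .stop_invalid("energy_density", "must be >= 0")
  structure(list(wavelength = wavelength, energy_density = energy_density,
                 phase_offset = phase_offset, active = active,
                 fluid_density = fluid_density,
                 fluid_compressibility = fluid_compressibility),
            class = "acoustic_config")
}

#' Acoustic energy density from drive voltage
#'
#' \eqn{E_{ac} = a V^2}.
#'
#' @param voltage drive voltage (V).
#' @param a proportionality constant (J/m^3/V^2, >= 0).
#' @return energy density in J/m^3.
#' @export
energyDensity <- function(voltage, a) {
  if (!is.numeric(a) || a < 0) .stop_invalid("a", "must be >= 0")
  a * voltage^2
}

#' Primary acoustic radiation force on a small particle
#'
#' \deqn{F_A = -\frac{2\pi V_p E_{ac}}{\lambda}\,\Phi(\beta,\rho)\,
#'   \sin\!\left(\frac{4\pi (y_p - \phi)}{\lambda}\right)}
#' with the particle volume \eqn{V_p = (4/3)\pi r^3} and \eqn{\phi} the
#' configured phase offset.  Valid for particles much smaller than the
#' wavelength; the sign convention makes the configured node positions
#' attractors for positive contrast.
#'
#' @param y_p lateral position(s) in metres, measured from the bottom wall.
#' @param particle a \code{\link{particleSpec}}.
#' @param cfg an \code{\link{acousticConfig}}.
#' @return force in newtons (vectorized over \code{y_p}).  An inactive
#'   configuration returns 0 with a notice.
#' @export
acousticRadiationForce <- function(y_p, particle, cfg) {
  if (!isTRUE(cfg$active)) {
    message("acoustic field inactive; returning zero force")
    return(rep(0, length(y_p)))
  }
  if (particle$radius > cfg$wavelength / 10)
    warning("particle radius is not small compared to the wavelength; ",
            "the radiation-force expression may not be valid")
  phi <- contrastFactor(particle$compressibility, cfg$fluid_compressibility,
                        particle$density, cfg$fluid_density)
  amp <- 2 * pi * particle$volume * cfg$energy_density / cfg$wavelength
  -amp * phi * sin(4 * pi * (y_p - cfg$phase_offset) / cfg$wavelength)
}

#' Stable pressure-node positions inside the channel
#'
#' Returns the lateral positions in \eqn{[0, W]} where the radiation force
#' vanishes with restoring slope for the given contrast sign.  With the
#' package's sign convention these are \eqn{\phi + k\lambda/2} for positive
#' contrast and \eqn{\phi + \lambda/4 + k\lambda/2} for negative contrast.
#'
#' @param cfg an \code{\link{acousticConfig}}.
#' @param channel_width channel width in metres.
#' @param contrast_sign +1 (node seekers) or -1 (antinode seekers).
#' @return sorted numeric vector of stable equilibrium positions (metres).
#'   No stable position inside the channel is a configuration error.
#' @export
pressureNodePositions <- function(cfg, channel_width, contrast_sign = 1) {
  if (channel_width <= 0) .stop_invalid("channel_width", "must be > 0")
  lam <- cfg$wavelength
  base <- cfg$phase_offset + if (contrast_sign >= 0) 0 else lam / 4
  kmin <- ceiling((0 - base) / (lam / 2))
  kmax <- floor((channel_width - base) / (lam / 2))
  if (kmax < kmin)
    .stop_config("no stable pressure node lies inside the channel")
  sort(base + (kmin:kmax) * lam / 2)
}
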