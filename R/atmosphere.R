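#' International Standard Atmosphere constants (troposphere)
#'
#' Sea-level density, temperature, temperature lapse rate, gravitational
#' acceleration and the specific gas constant of dry air used by the
#' altitude/density mapping.
#'
#' @format A named list with elements `rho0` (kg/m^3), `T0` (K),
#'   `lapse` (K/m), `g` (m/s^2), `R_gas` (J/(kg K)) and `mu` (Pa s,
#'   sea-level dynamic viscosity, treated as altitude-independent).
#' @export
isa_constants <- list(
  rho0  = 1.225,
  T0    = 288.15,
  lapse = 0.0065,
  g     = 9.80665,
  R_gas = 287.058,
  mu    = 1.81e-5
)

# density exponent g/(R*L) - 1 of the ISA troposphere power law
.isa_exponent <- function() {
  with(isa_constants, g / (R_gas * lapse) - 1)
}

#' Air density at a geopotential altitude
#'
#' ISA troposphere model: `rho(h) = rho0 * (1 - L h / T0)^(g/(R L) - 1)`.
#' Covers the troposphere only (0--11000 m), which comfortably contains the
#' monarch migration altitudes of interest (sea level to ~3200 m).
#'
#' @param h altitude in metres (vectorised), 0 <= h <= 11000.
#' @return air density in kg/m^3.
#' @examples
#' density_at_altitude(0)     # 1.225
#' density_at_altitude(3000)  # ~0.909
#' @export
density_at_altitude <- function(h) {
  if (any(!is.finite(h)) || any(h < 0) || any(h > 11000)) {
    stop("altitude must be finite and within [0, 11000] m (ISA troposphere)")
  }
  with(isa_constants, rho0 * (1 - lapse * h / T0)^.isa_exponent())
}

#' Altitude at which the ISA troposphere has a given air density
#'
#' Closed-form inverse of [density_at_altitude()].
#'
#' @param rho air density in kg/m^3 (vectorised), within the ISA troposphere
#'   range (density at 11000 m up to 1.225).
#' @return geopotential altitude in metres.
#' @export
altitude_at_density <- function(rho) {
  rho_min <- density_at_altitude(11000)
  if (any(!is.finite(rho)) || any(rho > isa_constants$rho0) || any(rho < rho_min)) {
    stop(sprintf("density must lie within the ISA troposphere range [%.4f, %.4f] kg/m^3",
                 rho_min, isa_constants$rho0))
  }
  with(isa_constants, T0 / lapse * (1 - (rho / rho0)^(1 / .isa_exponent())))
}

#' Ambient atmospheric state at an altitude
#'
#' @param h altitude in metres.
#' @param mu dynamic viscosity override in Pa s; defaults to the sea-level
#'   ISA value, treated as altitude-independent (the flow model assumes
#'   constant density and viscosity within a run).
#' @return an object of class `atmosphere_state` with fields `altitude_m`,
#'   `rho_air` and `mu`.
#' @export
atmosphere_state <- function(h, mu = isa_constants$mu) {
  stopifnot(length(h) == 1, is.finite(mu), mu > 0)
  structure(
    list(altitude_m = h, rho_air = density_at_altitude(h), mu = mu),
    class = "atmosphere_state"
  )
}

#' @export
print.atmosphere_state <- function(x, ...) {
  cat(sprintf("atmosphere_state: h = %.0f m, rho_air = %.4f kg/m^3, mu = %.3g Pa s\n",
              x$altitude_m, x$rho_air, x$mu))
  invisible(x)
}
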