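#' Wing morphology and material specification
#'
#' Container for the geometric and structural parameters of the
#' chordwise-flexible flat-plate wing model: a uniform linear-elastic strip of
#' thickness `hw` whose chordwise bending stiffness per unit span is
#' `E_chord * hw^3 / 12`.
#'
#' When `rho_w` is not supplied it is derived as `mw / Vw`. If it is supplied
#' together with `mw` and `Vw` it must agree with their quotient to within 5%
#' (measured values are typically reported rounded).
#'
#' @param R wing length (span of one wing), m.
#' @param c mean chord, m.
#' @param hw structural plate thickness, m.
#' @param mw wing mass, kg (optional provenance).
#' @param Vw wing volume, m^3 (optional provenance).
#' @param rho_w wing density, kg/m^3 (derived from `mw/Vw` when omitted).
#' @param E_chord chordwise effective elastic modulus, Pa.
#' @param E_span spanwise effective elastic modulus, Pa.
#' @param S planform area, m^2 (defaults to `2 * R * c`, both wings).
#' @return object of class `wing_spec`. Field `I_chord` holds the chordwise
#'   second moment of area per unit span, `hw^3/12` (m^4/m).
#' @examples
#' w <- wing_spec()
#' w$rho_w  # mass / volume
#' @export
wing_spec <- function(R = 0.05, c = 2.9e-2, hw = 1.6e-4,
                      mw = 1.5e-5, Vw = 4.82e-8, rho_w = NULL,
                      E_chord = 0.3e9, E_span = 2.5e9, S = NULL) {
  if (is.null(rho_w)) {
    if (is.null(mw) || is.null(Vw)) stop("either rho_w or both mw and Vw must be given")
    rho_w <- wing_density(mw, Vw)
  } else if (!is.null(mw) && !is.null(Vw)) {
    q <- mw / Vw
    if (abs(rho_w - q) / q > 0.05) {
      stop(sprintf("rho_w = %.4g disagrees with mw/Vw = %.4g by more than 5%%", rho_w, q))
    }
  }
  vals <- c(R = R, c = c, hw = hw, rho_w = rho_w, E_chord = E_chord, E_span = E_span)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all wing parameters must be finite and strictly positive")
  }
  if (is.null(S)) S <- 2 * R * c
  structure(
    list(R = R, c = c, S = S, hw = hw, mw = mw, Vw = Vw, rho_w = rho_w,
         E_chord = E_chord, E_span = E_span, I_chord = hw^3 / 12),
    class = "wing_spec"
  )
}

#' @export
print.wing_spec <- function(x, ...) {
  cat("wing_spec\n")
  cat(sprintf("  R = %.3g m, c = %.3g m, hw = %.3g m, S = %.3g m^2\n", x$R, x$c, x$hw, x$S))
  cat(sprintf("  rho_w = %.4g kg/m^3, E_chord = %.3g Pa, E_span = %.3g Pa\n",
              x$rho_w, x$E_chord, x$E_span))
  invisible(x)
}

#' Wing density from mass and volume
#'
#' @param mw wing mass, kg.
#' @param Vw wing volume, m^3.
#' @return density `mw / Vw` in kg/m^3.
#' @export
wing_density <- function(mw, Vw) {
  if (!is.finite(mw) || !is.finite(Vw) || mw <= 0 || Vw <= 0) {
    stop("mass and volume must be finite and strictly positive")
  }
  mw / Vw
}

#' Ambient flight condition
#'
#' Bundles the ambient state with the flight speed; the Reynolds number is
#' always recomputed as `rho_air * V * c / mu` and never stored independently.
#'
#' @param altitude altitude, m. Either `altitude` or `rho_air` must be given;
#'   the other is filled in through the standard-atmosphere model.
#' @param rho_air air density, kg/m^3.
#' @param V flight speed, m/s.
#' @param mu dynamic viscosity, Pa s.
#' @param c reference chord for the Reynolds number, m.
#' @return object of class `flight_condition` with fields `altitude`,
#'   `rho_air`, `mu`, `V` and `Re`.
#' @export
flight_condition <- function(altitude = NULL, rho_air = NULL, V,
                             mu = isa_constants$mu, c = 2.9e-2) {
  if (is.null(rho_air) && is.null(altitude)) stop("give altitude or rho_air")
  if (is.null(rho_air)) rho_air <- density_at_altitude(altitude)
  if (is.null(altitude)) altitude <- altitude_at_density(rho_air)
  stopifnot(V >= 0, rho_air > 0, mu > 0)
  structure(
    list(altitude = altitude, rho_air = rho_air, mu = mu, V = V,
         Re = rho_air * V * c / mu, c_ref = c),
    class = "flight_condition"
  )
}

#' @export
print.flight_condition <- function(x, ...) {
  cat(sprintf("flight_condition: h = %.0f m, rho = %.4f kg/m^3, V = %.3g m/s, Re = %.0f\n",
              x$altitude, x$rho_air, x$V, x$Re))
  invisible(x)
}
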