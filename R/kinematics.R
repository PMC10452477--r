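#' Prescribed leading-edge kinematics and stroke-plane geometry
#'
#' The leading edge plunges sinusoidally, `zeta(t) = zeta_a cos(2 pi f t)`,
#' along the stroke plane, which is tilted by `beta` from the vertical in the
#' earth frame (larger `beta` = stroke plane closer to horizontal; at
#' `beta = 0` the wing plunges vertically while flying horizontally).
#'
#' @param zeta_a plunge amplitude, m.
#' @param f flapping frequency, Hz.
#' @param beta stroke plane angle, rad, in `[0, pi/2]`.
#' @param psi_a angular flapping amplitude, rad (optional provenance).
#' @param r2 nondimensional radius of the second moment of wing area
#'   (optional provenance).
#' @param R wing length used with `psi_a`/`r2`, m.
#' @return object of class `kinematic_spec`.
#' @export
kinematic_spec <- function(zeta_a = 31e-3, f = 10, beta = 0,
                           psi_a = NULL, r2 = NULL, R = NULL) {
  stopifnot(zeta_a > 0, f > 0, beta >= 0, beta <= pi / 2 + 1e-12)
  if (!is.null(psi_a) && !is.null(r2) && !is.null(R)) {
    za <- amplitude_from_angular(R, r2, psi_a)
    if (abs(za - zeta_a) / zeta_a > 1e-6) {
      stop(sprintf("zeta_a = %.4g inconsistent with R*r2*sin(psi_a) = %.4g", zeta_a, za))
    }
  }
  structure(list(zeta_a = zeta_a, f = f, beta = beta,
                 psi_a = psi_a, r2 = r2),
            class = "kinematic_spec")
}

#' @export
print.kinematic_spec <- function(x, ...) {
  cat(sprintf("kinematic_spec: zeta_a = %.3g m, f = %.3g Hz, beta = %.1f deg\n",
              x$zeta_a, x$f, x$beta * 180 / pi))
  invisible(x)
}

#' Leading-edge position, velocity and acceleration
#'
#' @param spec a [kinematic_spec()].
#' @param t time, s (vectorised).
#' @return list with `zeta`, `zeta_dot`, `zeta_ddot`.
#' @export
le_motion <- function(spec, t) {
  om <- 2 * pi * spec$f
  list(zeta = spec$zeta_a * cos(om * t),
       zeta_dot = -om * spec$zeta_a * sin(om * t),
       zeta_ddot = -om^2 * spec$zeta_a * cos(om * t))
}

#' Plunge amplitude from the angular flapping amplitude
#'
#' `zeta_a = R * r2 * sin(psi_a)`, the translation amplitude of the radius of
#' the second moment of wing area.
#'
#' @param R wing length, m.
#' @param r2 nondimensional second-moment radius.
#' @param psi_a angular flapping amplitude, rad (< pi/2).
#' @return plunge amplitude, m.
#' @export
amplitude_from_angular <- function(R, r2, psi_a) {
  stopifnot(R > 0, r2 > 0, psi_a >= 0, psi_a < pi / 2)
  R * r2 * sin(psi_a)
}

#' Resolve solver-frame forces into earth-frame lift and thrust
#'
#' The solver frame has the chord along x' (leading edge into the oncoming
#' flow) and the plunge axis along y'. Tilting the stroke plane by `beta`
#' from vertical rotates the plate relative to the horizontal freestream so
#' that the mean flow meets the chord at incidence `+beta` (the geometry
#' behind the effective angle of attack `alpha - atan(zeta_dot/V) + beta`).
#' The earth-frame components are then
#' `lift = -Fx' sin(beta) + Fy' cos(beta)` (weight-opposing) and
#' `thrust = -Fx' cos(beta) - Fy' sin(beta)` (flight direction). The map is a
#' pure rotation: at `beta = 0` the plunge-axis force is the lift and the
#' chordwise (streamwise) force maps to the thrust axis.
#'
#' @param Fx_total solver-frame chordwise force, N.
#' @param Fy_total solver-frame plunge-axis force, N.
#' @param beta stroke plane angle, rad.
#' @return list with `lift` and `thrust`, N.
#' @export
resolve_forces <- function(Fx_total, Fy_total, beta) {
  list(lift = -Fx_total * sin(beta) + Fy_total * cos(beta),
       thrust = -Fx_total * cos(beta) - Fy_total * sin(beta))
}

#' Freestream velocity in the solver frame
#'
#' The horizontal freestream makes angle `(pi/2 - beta)` with the plunge
#' axis; its plunge-axis component `+V sin(beta)` is what gives the plate a
#' positive mean incidence at `beta > 0`.
#'
#' @param V flight speed, m/s.
#' @param beta stroke plane angle, rad.
#' @return numeric length-2 vector `(u_x', u_y')`.
#' @export
freestream_solver_frame <- function(V, beta) {
  c(V * cos(beta), V * sin(beta))
}
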