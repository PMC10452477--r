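#' Trapezoidal mean of a series over one flapping cycle
#'
#' @param t sample times, s.
#' @param y sampled values.
#' @param f flapping frequency, Hz.
#' @param cycle_index which cycle to average (1-based; default 3, past the
#'   start-up transients).
#' @return scalar cycle mean.
#' @export
cycle_average <- function(t, y, f, cycle_index = 3) {
  stopifnot(length(t) == length(y), f > 0, cycle_index >= 1)
  t0 <- (cycle_index - 1) / f
  t1 <- cycle_index / f
  tol <- 1e-9 / f
  if (min(t) > t0 + tol || max(t) < t1 - tol) {
    stop(sprintf("series does not cover cycle %d ([%.4g, %.4g] s)", cycle_index, t0, t1))
  }
  sel <- t >= t0 - tol & t <= t1 + tol
  tt <- t[sel]; yy <- y[sel]
  .trapz(tt, yy) / (tt[length(tt)] - tt[1])
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Cycle-averaged lift and thrust coefficients
#'
#' `CL = L / (0.5 rho V^2 c 2R)` and likewise for thrust, normalised by the
#' planform of both wings.
#'
#' @param L_bar cycle-mean lift, N.
#' @param T_bar cycle-mean thrust, N.
#' @param rho_air air density, kg/m^3.
#' @param V flight speed, m/s (> 0; hover has no dynamic-pressure scale).
#' @param c chord, m.
#' @param R wing length, m.
#' @return list with `CL_bar` and `CT_bar`.
#' @export
force_coefficients <- function(L_bar, T_bar, rho_air, V, c, R) {
  stopifnot(rho_air > 0, c > 0, R > 0)
  if (!is.finite(V) || V <= 0) {
    stop("V must be positive: coefficients are undefined at hover; report dimensional forces")
  }
  qS <- 0.5 * rho_air * V^2 * c * 2 * R
  list(CL_bar = L_bar / qS, CT_bar = T_bar / qS)
}

#' Aerodynamic/inertial power decomposition of a coupled solution
#'
#' Total actuation power `P = Paero + Pinertial` with
#' `Paero(t) = 2R * (-zeta_dot) * integral of F'_y dx` (plunge-axis fluid load
#' worked against the leading-edge actuation velocity) and
#' `Pinertial(t) = 2R * zeta_dot * integral of rho_w hw w_ddot dx`. Both
#' integrals are evaluated with the beam's consistent shape functions, so the
#' sum equals the leading-edge actuator force times the plunge velocity to
#' round-off.
#'
#' @param solution an [run_cycles()] solution.
#' @return data.frame with columns `t`, `P`, `Paero`, `Pinertial`, W.
#' @export
power_decomposition <- function(solution) {
  s <- solution$series
  twoR <- 2 * solution$wing$R
  Paero <- -twoR * s$zeta_dot * s$int_q
  Pin <- twoR * s$zeta_dot * s$int_mu_a
  data.frame(t = s$t, P = Paero + Pin, Paero = Paero, Pinertial = Pin)
}

#' Propulsive efficiency
#'
#' `eta = L_bar * mean(|zeta_dot|) / P_bar`; the velocity scale is the
#' cycle-mean absolute plunge speed `4 zeta_a f`.
#'
#' @param L_bar cycle-mean lift, N.
#' @param mean_abs_zeta_dot cycle-mean `|zeta_dot|`, m/s.
#' @param P_bar cycle-mean total power, W.
#' @return dimensionless efficiency.
#' @export
efficiency <- function(L_bar, mean_abs_zeta_dot, P_bar) {
  if (!is.finite(P_bar) || P_bar <= 0) stop("P_bar must be positive")
  L_bar * mean_abs_zeta_dot / P_bar
}

#' Effective angle of attack series
#'
#' `alpha_eff(t) = alpha(t) - atan(zeta_dot(t) / V) + beta`: the passive pitch
#' corrected for the flow direction induced by the plunge velocity, plus the
#' stroke-plane tilt.
#'
#' @param alpha_t pitch series, rad.
#' @param zeta_dot_t plunge velocity series, m/s.
#' @param V flight speed, m/s (> 0).
#' @param beta stroke plane angle, rad.
#' @param t optional time vector; with `f` a cycle mean is also returned.
#' @param f optional flapping frequency, Hz.
#' @param cycle_index cycle used for the mean.
#' @return list with `series` (rad) and, when `t` and `f` are given, `mean`.
#' @export
effective_aoa <- function(alpha_t, zeta_dot_t, V, beta, t = NULL, f = NULL,
                          cycle_index = 3) {
  if (!is.finite(V) || V <= 0) stop("V must be positive")
  series <- alpha_t - atan(zeta_dot_t / V) + beta
  out <- list(series = series)
  if (!is.null(t) && !is.null(f)) {
    out$mean <- cycle_average(t, series, f, cycle_index)
  }
  out
}

#' Cycle-averaged performance of a coupled run
#'
#' Reduces an aeroelastic solution to the cycle-averaged metrics: mean lift
#' and thrust, their coefficients, the aerodynamic/inertial power split,
#' propulsive efficiency, mean effective angle of attack, and the
#' first-harmonic pitch amplitude and phase.
#'
#' @param solution a [run_cycles()] solution.
#' @param flight a [flight_condition()].
#' @param cycle_index cycle to average (default 3).
#' @return object of class `cycle_performance`.
#' @export
cycle_performance <- function(solution, flight, cycle_index = 3) {
  s <- solution$series
  kin <- solution$kinematics
  wing <- solution$wing
  f <- kin$f
  L_bar <- cycle_average(s$t, s$L, f, cycle_index)
  T_bar <- cycle_average(s$t, s$Th, f, cycle_index)
  pw <- power_decomposition(solution)
  P_bar <- cycle_average(pw$t, pw$P, f, cycle_index)
  Paero_bar <- cycle_average(pw$t, pw$Paero, f, cycle_index)
  Pin_bar <- cycle_average(pw$t, pw$Pinertial, f, cycle_index)
  coefs <- if (flight$V > 0) {
    force_coefficients(L_bar, T_bar, flight$rho_air, flight$V, wing$c, wing$R)
  } else list(CL_bar = NA_real_, CT_bar = NA_real_)
  mean_abs_zd <- 4 * kin$zeta_a * f
  eta <- if (P_bar > 0) efficiency(L_bar, mean_abs_zd, P_bar) else NA_real_
  aeff <- if (flight$V > 0) {
    effective_aoa(s$alpha, s$zeta_dot, flight$V, kin$beta, s$t, f, cycle_index)$mean
  } else NA_real_
  sel <- s$t >= (cycle_index - 1) / f - 1e-12
  fh <- first_harmonic_fit(s$alpha[sel], s$t[sel], f)
  structure(
    list(L_bar = L_bar, T_bar = T_bar,
         CL_bar = coefs$CL_bar, CT_bar = coefs$CT_bar,
         P_bar = P_bar, Paero_bar = Paero_bar, Pinertial_bar = Pin_bar,
         eta = eta, alpha_eff_bar = aeff,
         alpha_a = fh$alpha_a, phi = fh$phi,
         cycle_index = cycle_index),
    class = "cycle_performance"
  )
}

#' @export
print.cycle_performance <- function(x, ...) {
  cat(sprintf("cycle_performance (cycle %d)\n", x$cycle_index))
  cat(sprintf("  L = %.3g mN, T = %.3g mN, CL = %.3g, CT = %.3g\n",
              1e3 * x$L_bar, 1e3 * x$T_bar, x$CL_bar, x$CT_bar))
  cat(sprintf("  P = %.3g mW (aero %.3g + inertial %.3g), eta = %.3g\n",
              1e3 * x$P_bar, 1e3 * x$Paero_bar, 1e3 * x$Pinertial_bar, x$eta))
  cat(sprintf("  alpha_eff = %.3g deg, alpha_a = %.3g deg, phi = %.3g rad\n",
              x$alpha_eff_bar * 180 / pi, x$alpha_a * 180 / pi, x$phi))
  invisible(x)
}
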