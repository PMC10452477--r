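#' Measurement noise model for synthetic bench data
#'
#' Multiplicative per-measurement force noise plus lognormal per-specimen
#' stiffness variability. The defaults are chosen so that the 4-point
#' mean-force stiffness fits land, in expectation, near the scatter observed
#' on real wings (coefficient of determination ~0.75 chordwise, ~0.97
#' spanwise): chordwise forces are an order of magnitude smaller and
#' correspondingly noisier.
#'
#' @param force_sd_frac per-measurement multiplicative force noise (sd as a
#'   fraction of the true force), named for each direction.
#' @param stiffness_sd_log lognormal sd of per-specimen stiffness multipliers.
#' @param seed RNG seed.
#' @return object of class `measurement_noise_model`.
#' @export
measurement_noise_model <- function(force_sd_frac = c(spanwise = 0.10, chordwise = 0.32),
                                    stiffness_sd_log = 0.08, seed = 1) {
  stopifnot(all(force_sd_frac >= 0), stiffness_sd_log >= 0)
  structure(list(force_sd_frac = force_sd_frac,
                 stiffness_sd_log = stiffness_sd_log, seed = seed),
            class = "measurement_noise_model")
}

#' Generate synthetic force-deflection records
#'
#' Forward model: a uniform linear-elastic cantilever strip (spanwise modulus
#' 2.5 GPa over strip width `c`, chordwise modulus 0.3 GPa over width `c/4`;
#' see [strip_width()]) loaded at the 70% station, at prescribed deflections
#' of 3, 4, 5 and 6 mm, with multiplicative measurement noise and lognormal
#' specimen-to-specimen stiffness variability. Records are the mean forces
#' across specimens at each deflection, the same reduction applied to the
#' bench data.
#'
#' @param direction `"spanwise"` or `"chordwise"`.
#' @param n_specimens specimens averaged per deflection.
#' @param noise a [measurement_noise_model()]; its `seed` drives the RNG.
#' @param wing a [wing_spec()] supplying geometry and ground-truth moduli.
#' @param deflections_m deflection levels, m.
#' @param raw if `TRUE`, return one row per specimen and deflection instead
#'   of specimen means.
#' @return data.frame with columns `direction`, `l_m`, `delta_m`, `force_N`, `n`.
#' @export
gen_force_deflection <- function(direction = c("chordwise", "spanwise"),
                                 n_specimens = 5,
                                 noise = measurement_noise_model(),
                                 wing = wing_spec(),
                                 deflections_m = c(3, 4, 5, 6) * 1e-3,
                                 raw = FALSE) {
  direction <- match.arg(direction)
  stopifnot(n_specimens >= 1)
  geom <- .strip_geometry(wing, direction)
  E <- if (direction == "spanwise") wing$E_span else wing$E_chord
  I_strip <- strip_width(wing, direction) * wing$hw^3 / 12
  k_true <- 3 * E * I_strip / geom$l^3
  sd_frac <- noise$force_sd_frac[[direction]]

  set.seed(noise$seed + if (direction == "spanwise") 1000L else 0L)
  spec_mult <- exp(stats::rnorm(n_specimens, 0, noise$stiffness_sd_log))
  rows <- expand.grid(specimen = seq_len(n_specimens), delta_m = deflections_m)
  F_true <- k_true * rows$delta_m * spec_mult[rows$specimen]
  F_meas <- F_true * (1 + stats::rnorm(nrow(rows), 0, sd_frac))
  rows$force_N <- F_meas
  rows$direction <- direction
  rows$l_m <- geom$l
  if (raw) {
    rows$n <- 1L
    return(rows[, c("direction", "l_m", "delta_m", "force_N", "n", "specimen")])
  }
  agg <- stats::aggregate(force_N ~ delta_m, data = rows, FUN = mean)
  data.frame(direction = direction, l_m = geom$l, delta_m = agg$delta_m,
             force_N = agg$force_N, n = n_specimens)
}

#' Generate synthetic free-flight observations versus altitude
#'
#' Emulates field observations in which flight speed falls significantly
#' with altitude: `V(h)` decreases linearly from ~1.4 m/s near sea level to
#' ~0.7 m/s at 3000 m, with seeded Gaussian noise, and the Reynolds number
#' follows `Re = rho_air(h) V c / mu`.
#'
#' @param altitudes altitudes, m, within \[0, 3200\].
#' @param seed RNG seed.
#' @param noise_sd flight-speed noise sd, m/s.
#' @param c reference chord, m.
#' @param mu dynamic viscosity, Pa s.
#' @return data.frame with columns `h`, `V`, `Re`.
#' @export
gen_flight_observations <- function(altitudes, seed = 1, noise_sd = 0.05,
                                    c = 2.9e-2, mu = isa_constants$mu) {
  if (any(altitudes < 0) || any(altitudes > 3200)) {
    stop("altitudes must lie within [0, 3200] m")
  }
  set.seed(seed)
  V <- 1.4 - (0.7 / 3000) * altitudes + stats::rnorm(length(altitudes), 0, noise_sd)
  V <- pmax(V, 0.3)
  rho <- density_at_altitude(altitudes)
  data.frame(h = altitudes, V = V, Re = rho * V * c / mu)
}

#' Quasi-steady aerodynamic oracle configuration
#'
#' The oracle is the fast stand-in load model used for desk-scale coupled
#' runs and as a test scaffold for the coupling and performance machinery;
#' it is not a claim about the full viscous flow. Per chord station it
#' combines a non-circulatory added-mass reaction
#' `-(pi/4) rho c a_n` per unit chord (total `pi/4 rho c^2 a` per unit span
#' for uniform acceleration) and a quasi-steady circulatory normal force
#' `0.5 rho |u_rel|^2 Cn` per unit chord with `Cn = 2 pi sin(a) |cos(a)|`,
#' the flat-plate normal-force law whose `sin cos` form self-limits past
#' stall.
#'
#' @param added_mass_coef added-mass coefficient (default `pi/4`, flat plate).
#' @param cn_slope circulatory normal-force slope (default `2 pi`).
#' @param rotational include a rotational-circulation term driven by the
#'   local pitch rate (default off).
#' @return object of class `oracle_config`.
#' @export
oracle_config <- function(added_mass_coef = pi / 4, cn_slope = 2 * pi,
                          rotational = FALSE) {
  structure(list(added_mass_coef = added_mass_coef, cn_slope = cn_slope,
                 rotational = rotational),
            class = "oracle_config")
}

#' Quasi-steady oracle loads on the deforming plate
#'
#' @param x chord stations, m.
#' @param w,w_dot,w_ddot transverse displacement, velocity and acceleration
#'   at the stations, m, m/s, m/s^2 (solver-frame y').
#' @param slope local chordwise slope `dw/dx` at the stations.
#' @param slope_dot local slope rate, 1/s (used only by the rotational term).
#' @param uinf freestream velocity in the solver frame, length-2.
#' @param rho_air air density, kg/m^3.
#' @param c chord, m.
#' @param cfg an [oracle_config()].
#' @return list with per-station solver-frame force components per unit chord
#'   per unit span `fx`, `fy` (N/m^2), the transverse beam load `q = fy`, and
#'   integrated per-unit-span forces `Fx`, `Fy` (N/m).
#' @export
oracle_loads <- function(x, w, w_dot, w_ddot, slope, slope_dot = NULL,
                         uinf, rho_air, c, cfg = oracle_config()) {
  theta <- atan(slope)
  ct <- cos(theta); st <- sin(theta)
  # air velocity relative to the plate surface
  ur_x <- uinf[1]
  ur_y <- uinf[2] - w_dot
  ut <- ur_x * ct + ur_y * st    # tangential
  un <- -ur_x * st + ur_y * ct   # normal
  # circulatory: 0.5 rho |u|^2 * cn_slope sin(a)|cos(a)| = 0.5 cn_slope rho un |ut|
  f_circ <- 0.5 * cfg$cn_slope * rho_air * un * abs(ut)
  # added mass reaction to the normal acceleration
  a_n <- w_ddot * ct
  f_am <- -cfg$added_mass_coef * rho_air * c * a_n
  f_n <- f_circ + f_am
  if (isTRUE(cfg$rotational) && !is.null(slope_dot)) {
    f_n <- f_n + pi * rho_air * c * ut * slope_dot * (0.75 - x / c)
  }
  fx <- -f_n * st
  fy <- f_n * ct
  list(fx = fx, fy = fy, q = fy,
       Fx = .trapz(x, fx), Fy = .trapz(x, fy))
}
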