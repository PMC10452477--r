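#' Partitioned-coupling configuration
#'
#' @param tol_w inner displacement convergence tolerance as a fraction of the
#'   chord (max-norm of the displacement change between inner iterations).
#' @param max_inner maximum inner iterations per time step.
#' @param relaxation `"aitken"` (dynamic) or `"fixed"`.
#' @param omega0 initial (or fixed) relaxation factor in (0, 1].
#' @return object of class `coupling_config`.
#' @export
coupling_config <- function(tol_w = 1e-6, max_inner = 50,
                            relaxation = c("aitken", "fixed"), omega0 = 0.5) {
  relaxation <- match.arg(relaxation)
  stopifnot(tol_w > 0, max_inner >= 1, omega0 > 0, omega0 <= 1)
  structure(list(tol_w = tol_w, max_inner = max_inner,
                 relaxation = relaxation, omega0 = omega0),
            class = "coupling_config")
}

#' Aitken-relaxed fixed-point iteration
#'
#' Solves `d = g(d)` by relaxed fixed-point iteration with Aitken's delta^2
#' dynamic relaxation (or a fixed factor). This is the inner loop of the
#' partitioned fluid-structure advance.
#'
#' @param g fixed-point map taking and returning a numeric vector.
#' @param d0 starting vector.
#' @param tol absolute max-norm tolerance on the residual `g(d) - d`.
#' @param max_inner iteration cap.
#' @param omega0 initial/fixed relaxation factor.
#' @param relaxation `"aitken"` or `"fixed"`.
#' @return list with the solution `d`, iteration count `n_inner` and the
#'   residual max-norm history `residuals`.
#' @export
aitken_solve <- function(g, d0, tol, max_inner = 50, omega0 = 0.5,
                         relaxation = "aitken") {
  d <- d0
  omega <- omega0
  r_prev <- NULL
  res_hist <- numeric(0)
  for (k in seq_len(max_inner)) {
    d_tilde <- g(d)
    r <- d_tilde - d
    res <- max(abs(r))
    res_hist <- c(res_hist, res)
    if (res <= tol) {
      return(list(d = d_tilde, n_inner = k, residuals = res_hist))
    }
    if (relaxation == "aitken" && !is.null(r_prev)) {
      dr <- r - r_prev
      denom <- sum(dr^2)
      if (denom > 0) omega <- -omega * sum(r_prev * dr) / denom
      omega <- max(min(omega, 2), 1e-4)
    }
    d <- d + omega * r
    r_prev <- r
  }
  stop(sprintf("inner coupling iterations did not converge in %d steps; residual history: %s",
               max_inner, paste(signif(res_hist, 3), collapse = " ")))
}

#' One tightly coupled fluid-structure time step
#'
#' Advances the beam and the load provider from `t` to `t + dt` with serial
#' (fluid-first) staggering inside an Aitken-relaxed fixed-point loop on the
#' beam's free displacement vector: loads are evaluated on the candidate
#' kinematics, the beam is re-solved, and the displacement update is relaxed
#' until the max-norm change is below `tol_w * chord`.
#'
#' @param mesh a [beam_mesh()].
#' @param state the [beam_state_init()] state at time `t`.
#' @param provider a load provider (see [oracle_provider()]), with `eval`
#'   and `commit` functions.
#' @param dt time step, s.
#' @param bc list of `zeta`, `zeta_dot`, `zeta_ddot` at `t + dt`.
#' @param cfg a [coupling_config()].
#' @param op optional pre-factorised [newmark_operator()].
#' @return list with the new `state`, the converged `loads`, `n_inner` and
#'   `residuals`.
#' @export
coupled_step <- function(mesh, state, provider, dt, bc,
                         cfg = coupling_config(), op = NULL) {
  if (is.null(op)) op <- newmark_operator(mesh, dt)
  fr <- mesh$free
  d0 <- state$d[fr]; v0 <- state$v[fr]; a0 <- state$a[fr]
  last <- new.env(parent = emptyenv())

  kin_from_d <- function(df) {
    af <- (4 / dt^2) * (df - d0) - (4 / dt) * v0 - a0
    vf <- v0 + dt / 2 * (a0 + af)
    d <- state$d; v <- state$v; a <- state$a
    d[fr] <- df; v[fr] <- vf; a[fr] <- af
    d[mesh$constrained] <- c(bc$zeta, 0)
    v[mesh$constrained] <- c(bc$zeta_dot, 0)
    a[mesh$constrained] <- c(bc$zeta_ddot, 0)
    list(w = d[mesh$w_dofs], w_dot = v[mesh$w_dofs], w_ddot = a[mesh$w_dofs],
         slope = d[mesh$theta_dofs], slope_dot = v[mesh$theta_dofs])
  }

  g <- function(df) {
    kin <- kin_from_d(df)
    loads <- provider$eval(kin, state$t + dt, dt)
    st <- step_dynamic(mesh, state, loads$q, dt, bc, op)
    last$loads <- loads
    last$state <- st
    st$d[fr]
  }

  # predictor: constant-velocity extrapolation
  dguess <- d0 + dt * v0 + 0.5 * dt^2 * a0
  sol <- aitken_solve(g, dguess, tol = cfg$tol_w * mesh$length,
                      max_inner = cfg$max_inner, omega0 = cfg$omega0,
                      relaxation = cfg$relaxation)
  # ensure committed state corresponds to the final displacement
  if (max(abs(last$state$d[fr] - sol$d)) > 0) invisible(g(sol$d))
  provider$commit()
  list(state = last$state, loads = last$loads,
       n_inner = sol$n_inner, residuals = sol$residuals)
}

#' Quasi-steady oracle load provider
#'
#' Wraps [oracle_loads()] in the provider interface consumed by
#' [coupled_step()]: `eval(kin, t, dt)` returns the loads for candidate plate
#' kinematics and `commit()` is a no-op (the oracle is stateless).
#'
#' @param mesh a [beam_mesh()].
#' @param flight a [flight_condition()].
#' @param beta stroke plane angle, rad.
#' @param cfg an [oracle_config()].
#' @return provider list with `eval` and `commit`.
#' @export
oracle_provider <- function(mesh, flight, beta, cfg = oracle_config()) {
  uinf <- freestream_solver_frame(flight$V, beta)
  x <- mesh$node_x
  c_chord <- mesh$length
  list(
    eval = function(kin, t, dt) {
      oracle_loads(x, kin$w, kin$w_dot, kin$w_ddot, kin$slope, kin$slope_dot,
                   uinf = uinf, rho_air = flight$rho_air, c = c_chord, cfg = cfg)
    },
    commit = function() invisible(NULL),
    mode = "oracle"
  )
}

#' Run a coupled aeroelastic simulation over full flapping cycles
#'
#' Simulates `n_cycles` cycles from rest (cosine start at `zeta(0) = zeta_a`)
#' with the partitioned coupling of [coupled_step()], in either the fast
#' quasi-steady `"oracle"` mode or the immersed-boundary Navier-Stokes
#' `"cfd"` mode. Cycle-averaged quantities should be taken from the final
#' cycle; a periodicity metric (relative change in mean lift between the last
#' two cycles) is reported.
#'
#' @param wing a [wing_spec()].
#' @param kin a [kinematic_spec()].
#' @param flight a [flight_condition()].
#' @param n_cycles number of flapping cycles.
#' @param mode `"oracle"` or `"cfd"`.
#' @param n_elements beam elements.
#' @param steps_per_cycle time steps per flapping period.
#' @param coupling a [coupling_config()].
#' @param oracle_cfg an [oracle_config()] (oracle mode).
#' @param cfd list of solver options for [ib_flow_provider()] (cfd mode).
#' @return object of class `aeroelastic_solution`: a per-step `series`
#'   data.frame (`t`, `zeta`, `zeta_dot`, `w_te`, `alpha`, per-unit-span
#'   solver-frame forces `Fx`, `Fy`, lift `L`, thrust `Th`, power bookkeeping
#'   integrals `int_q`, `int_mu_a`, actuator `reaction`, `n_inner`), plus the
#'   inputs and a `periodicity` metric.
#' @export
run_cycles <- function(wing, kin, flight, n_cycles = 3,
                       mode = c("oracle", "cfd"),
                       n_elements = 16, steps_per_cycle = 200,
                       coupling = coupling_config(),
                       oracle_cfg = oracle_config(),
                       cfd = list()) {
  mode <- match.arg(mode)
  EIp <- wing$E_chord * wing$I_chord
  mu_m <- wing$rho_w * wing$hw
  mesh <- beam_mesh(n_elements, wing$c, EIp, mu_m)
  dt <- 1 / (kin$f * steps_per_cycle)
  op <- newmark_operator(mesh, dt)

  provider <- if (mode == "oracle") {
    oracle_provider(mesh, flight, kin$beta, oracle_cfg)
  } else {
    do.call(ib_flow_provider, c(list(mesh = mesh, flight = flight, kin = kin), cfd))
  }

  m0 <- le_motion(kin, 0)
  state <- beam_state_init(mesh, bc = list(zeta = m0$zeta, zeta_dot = m0$zeta_dot,
                                           zeta_ddot = m0$zeta_ddot))
  n_steps <- n_cycles * steps_per_cycle
  rec <- matrix(NA_real_, n_steps + 1, 13)
  colnames(rec) <- c("t", "zeta", "zeta_dot", "w_te", "alpha", "Fx", "Fy",
                     "L", "Th", "int_q", "int_mu_a", "reaction", "n_inner")
  te_dof <- mesh$ndof - 1
  rf0 <- resolve_forces(0, 0, kin$beta)
  rec[1, ] <- c(0, m0$zeta, m0$zeta_dot, state$d[te_dof],
                passive_pitch(state$d[te_dof], m0$zeta, wing$c),
                0, 0, 2 * wing$R * rf0$lift, 2 * wing$R * rf0$thrust, 0, 0, 0, 0)
  twoR <- 2 * wing$R
  for (i in seq_len(n_steps)) {
    t1 <- i * dt
    m <- le_motion(kin, t1)
    bc <- list(zeta = m$zeta, zeta_dot = m$zeta_dot, zeta_ddot = m$zeta_ddot)
    stp <- coupled_step(mesh, state, provider, dt, bc, coupling, op)
    state <- stp$state
    ld <- stp$loads
    rf <- resolve_forces(ld$Fx, ld$Fy, kin$beta)
    rec[i + 1, ] <- c(t1, m$zeta, m$zeta_dot, state$d[te_dof],
                      passive_pitch(state$d[te_dof], m$zeta, wing$c),
                      ld$Fx, ld$Fy, twoR * rf$lift, twoR * rf$thrust,
                      attr(state, "int_q"), attr(state, "int_mu_a"),
                      attr(state, "reaction_force"), stp$n_inner)
  }
  series <- as.data.frame(rec)

  periodicity <- NA_real_
  if (n_cycles >= 2) {
    f <- kin$f
    L_last <- cycle_average(series$t, series$L, f, n_cycles)
    L_prev <- cycle_average(series$t, series$L, f, n_cycles - 1)
    scale <- max(abs(series$L[series$t >= (n_cycles - 1) / f]), 1e-300)
    periodicity <- abs(L_last - L_prev) / scale
  }
  structure(
    list(series = series, wing = wing, kinematics = kin, flight = flight,
         mode = mode, n_cycles = n_cycles, n_elements = n_elements,
         steps_per_cycle = steps_per_cycle, periodicity = periodicity,
         mean_inner = mean(series$n_inner[-1])),
    class = "aeroelastic_solution"
  )
}

#' @export
print.aeroelastic_solution <- function(x, ...) {
  cat(sprintf("aeroelastic_solution (%s): %d cycles x %d steps, %d beam elements\n",
              x$mode, x$n_cycles, x$steps_per_cycle, x$n_elements))
  cat(sprintf("  periodicity (last-cycle mean-lift drift): %.3g; mean inner iterations: %.1f\n",
              x$periodicity, x$mean_inner))
  invisible(x)
}

#' Export the time series of a coupled run to CSV
#'
#' @param solution an [run_cycles()] solution.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path) {
  utils::write.csv(solution$series, path, row.names = FALSE)
  invisible(path)
}
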