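#' Hermite-cubic Euler-Bernoulli beam mesh
#'
#' Discretises the chordwise beam equation
#' `rho_w hw d2w/dt2 + E I d4w/dx4 = p` (per unit span) with standard
#' two-node Hermite cubic elements. Degrees of freedom are interleaved
#' `(w_1, theta_1, w_2, theta_2, ...)` with `x = 0` at the leading edge.
#'
#' @param n_elements number of elements.
#' @param length beam length (chord for chordwise bending), m.
#' @param EI bending stiffness per unit span, N m^2 / m.
#' @param mu_m mass per unit length per unit span (`rho_w * hw`), kg/m^2.
#' @return object of class `beam_mesh` with assembled dense mass and stiffness
#'   matrices `M`, `K`, node coordinates `node_x` and bookkeeping of the
#'   clamped leading-edge DOFs.
#' @export
beam_mesh <- function(n_elements, length, EI, mu_m) {
  stopifnot(n_elements >= 1, length > 0, EI > 0, mu_m > 0)
  n_nodes <- n_elements + 1
  ndof <- 2 * n_nodes
  h <- length / n_elements
  Ke <- EI / h^3 * matrix(c(
    12,    6 * h,   -12,    6 * h,
    6 * h, 4 * h^2, -6 * h, 2 * h^2,
    -12,  -6 * h,    12,   -6 * h,
    6 * h, 2 * h^2, -6 * h, 4 * h^2), 4, 4, byrow = TRUE)
  Me <- mu_m * h / 420 * matrix(c(
    156,     22 * h,   54,     -13 * h,
    22 * h,  4 * h^2,  13 * h, -3 * h^2,
    54,      13 * h,   156,    -22 * h,
    -13 * h, -3 * h^2, -22 * h, 4 * h^2), 4, 4, byrow = TRUE)
  K <- matrix(0, ndof, ndof)
  M <- matrix(0, ndof, ndof)
  for (e in seq_len(n_elements)) {
    idx <- (2 * e - 1):(2 * e + 2)
    K[idx, idx] <- K[idx, idx] + Ke
    M[idx, idx] <- M[idx, idx] + Me
  }
  # leading-edge node clamped: prescribed translation, zero slope
  constrained <- c(1L, 2L)
  free <- setdiff(seq_len(ndof), constrained)
  structure(
    list(n_elements = n_elements, length = length, EI = EI, mu_m = mu_m,
         node_x = seq(0, length, length.out = n_nodes), h = h,
         ndof = ndof, M = M, K = K, free = free, constrained = constrained,
         w_dofs = seq(1L, ndof, by = 2L), theta_dofs = seq(2L, ndof, by = 2L)),
    class = "beam_mesh"
  )
}

# Hermite shape functions on an element of length h at local coordinate xi in [0,1]
.hermite_shape <- function(xi, h) {
  c(1 - 3 * xi^2 + 2 * xi^3,
    h * (xi - 2 * xi^2 + xi^3),
    3 * xi^2 - 2 * xi^3,
    h * (-xi^2 + xi^3))
}

#' Consistent nodal vector for a point load
#'
#' @param mesh a [beam_mesh()].
#' @param F point force per unit span, N/m.
#' @param x_load load position along the beam, m.
#' @return full-length consistent load vector.
#' @export
point_load_vector <- function(mesh, F, x_load) {
  stopifnot(x_load >= 0, x_load <= mesh$length + 1e-12)
  e <- min(max(1L, ceiling(x_load / mesh$h - 1e-12)), mesh$n_elements)
  xi <- (x_load - (e - 1) * mesh$h) / mesh$h
  f <- numeric(mesh$ndof)
  idx <- (2 * e - 1):(2 * e + 2)
  f[idx] <- f[idx] + F * .hermite_shape(xi, mesh$h)
  f
}

#' Consistent nodal vector for a distributed transverse load
#'
#' The load `q` is given at the nodes (N/m per unit span) and interpolated
#' linearly within each element.
#'
#' @param mesh a [beam_mesh()].
#' @param q nodal load values, length `n_elements + 1`.
#' @return full-length consistent load vector.
#' @export
distributed_load_vector <- function(mesh, q) {
  stopifnot(length(q) == mesh$n_elements + 1)
  h <- mesh$h
  f <- numeric(mesh$ndof)
  for (e in seq_len(mesh$n_elements)) {
    q1 <- q[e]; q2 <- q[e + 1]
    fe <- c(h * (7 * q1 / 20 + 3 * q2 / 20),
            h^2 * (q1 / 20 + q2 / 30),
            h * (3 * q1 / 20 + 7 * q2 / 20),
            -h^2 * (q2 / 20 + q1 / 30))
    idx <- (2 * e - 1):(2 * e + 2)
    f[idx] <- f[idx] + fe
  }
  f
}

#' Static cantilever solve
#'
#' Solves `EI w'''' = f` with the leading edge clamped (`w = 0`, `w' = 0`)
#' for a point load, returning the nodal solution and an evaluator.
#'
#' @param mesh a [beam_mesh()].
#' @param F point load per unit span, N/m.
#' @param x_load load position, m.
#' @return list with nodal displacements `w`, slopes `theta`, the full DOF
#'   vector `d`, and `w_at(x)` interpolating the Hermite solution.
#' @export
static_solve <- function(mesh, F, x_load) {
  f <- point_load_vector(mesh, F, x_load)
  d <- numeric(mesh$ndof)
  Kff <- mesh$K[mesh$free, mesh$free]
  d[mesh$free] <- solve(Kff, f[mesh$free])
  list(w = d[mesh$w_dofs], theta = d[mesh$theta_dofs], d = d,
       w_at = function(x) beam_interpolate(mesh, d, x))
}

#' Evaluate the Hermite displacement field at arbitrary positions
#'
#' @param mesh a [beam_mesh()].
#' @param d full DOF vector.
#' @param x positions, m (vectorised).
#' @return displacements at `x`.
#' @export
beam_interpolate <- function(mesh, d, x) {
  vapply(x, function(xx) {
    e <- min(max(1L, ceiling(xx / mesh$h - 1e-12)), mesh$n_elements)
    xi <- (xx - (e - 1) * mesh$h) / mesh$h
    idx <- (2 * e - 1):(2 * e + 2)
    sum(.hermite_shape(xi, mesh$h) * d[idx])
  }, numeric(1))
}

#' In-vacuo bending natural frequencies of the clamped-free beam
#'
#' @param mesh a [beam_mesh()].
#' @param n_modes number of modes to return.
#' @return natural frequencies in Hz, ascending.
#' @export
beam_natural_frequencies <- function(mesh, n_modes = 3) {
  Kff <- mesh$K[mesh$free, mesh$free]
  Mff <- mesh$M[mesh$free, mesh$free]
  # symmetric generalized eigenproblem via Cholesky of M
  L <- t(chol(Mff))
  A <- forwardsolve(L, t(forwardsolve(L, Kff)))
  A <- (A + t(A)) / 2
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(pmax(ev[seq_len(n_modes)], 0)) / (2 * pi)
}

#' Initialise a beam state with a prescribed leading-edge condition
#'
#' Acceleration is made consistent with the equations of motion at t = 0.
#'
#' @param mesh a [beam_mesh()].
#' @param bc list with `zeta`, `zeta_dot`, `zeta_ddot` at t = 0.
#' @param q nodal transverse load at t = 0 (default zero).
#' @param rigid logical; start from a rigid-plunge shape (`w = zeta`) rather
#'   than zero elastic deformation away from the LE.
#' @return object of class `beam_state` with full vectors `d`, `v`, `a` and time `t`.
#' @export
beam_state_init <- function(mesh, bc = list(zeta = 0, zeta_dot = 0, zeta_ddot = 0),
                            q = NULL, rigid = TRUE) {
  d <- numeric(mesh$ndof); v <- numeric(mesh$ndof); a <- numeric(mesh$ndof)
  if (rigid) {
    d[mesh$w_dofs] <- bc$zeta
    v[mesh$w_dofs] <- bc$zeta_dot
  }
  d[1] <- bc$zeta; d[2] <- 0
  v[1] <- bc$zeta_dot; v[2] <- 0
  a[1] <- bc$zeta_ddot; a[2] <- 0
  f <- if (is.null(q)) numeric(mesh$ndof) else distributed_load_vector(mesh, q)
  fr <- mesh$free; cn <- mesh$constrained
  rhs <- f[fr] - mesh$K[fr, fr] %*% d[fr] - mesh$K[fr, cn] %*% d[cn] - mesh$M[fr, cn] %*% a[cn]
  a[fr] <- solve(mesh$M[fr, fr], rhs)
  structure(list(d = d, v = v, a = a, t = 0), class = "beam_state")
}

#' Pre-factorised Newmark operator
#'
#' Average-acceleration Newmark (beta = 1/4, gamma = 1/2), no structural
#' damping. The effective stiffness is factorised once per time step size.
#'
#' @param mesh a [beam_mesh()].
#' @param dt time step, s.
#' @return list holding the Cholesky factor of the effective stiffness.
#' @export
newmark_operator <- function(mesh, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  fr <- mesh$free
  Keff <- mesh$K[fr, fr] + (4 / dt^2) * mesh$M[fr, fr]
  list(dt = dt, R = chol(Keff))
}

#' Advance the beam one Newmark step under a prescribed LE motion
#'
#' The leading-edge translation DOF follows `bc$zeta` exactly and the LE slope
#' is clamped to zero; all other DOFs satisfy `M a + K d = f` with the
#' consistent load vector of the nodal transverse load `q` at `t + dt`.
#'
#' @param mesh a [beam_mesh()].
#' @param state a [beam_state_init()] state at time t.
#' @param q nodal transverse load (N/m per unit span) at `t + dt`.
#' @param dt time step, s.
#' @param bc list with `zeta`, `zeta_dot`, `zeta_ddot` evaluated at `t + dt`.
#' @param op optional pre-factorised [newmark_operator()] for this `dt`.
#' @return new `beam_state` at `t + dt`; attribute fields `reaction_force`
#'   (actuator transverse force at the LE, per unit span), `int_q`
#'   (`integral of q dx`) and `int_mu_a` (`integral of mu_m w_ddot dx`) are
#'   attached for power bookkeeping.
#' @export
step_dynamic <- function(mesh, state, q, dt, bc, op = NULL) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (is.null(op)) op <- newmark_operator(mesh, dt)
  fr <- mesh$free; cn <- mesh$constrained
  f <- distributed_load_vector(mesh, q)

  d0 <- state$d; v0 <- state$v; a0 <- state$a
  dc <- c(bc$zeta, 0); ac <- c(bc$zeta_ddot, 0); vc <- c(bc$zeta_dot, 0)

  rhs <- f[fr] -
    mesh$K[fr, cn] %*% dc -
    mesh$M[fr, cn] %*% ac +
    mesh$M[fr, fr] %*% ((4 / dt^2) * d0[fr] + (4 / dt) * v0[fr] + a0[fr])
  d1f <- backsolve(op$R, forwardsolve(t(op$R), rhs))

  d1 <- numeric(mesh$ndof); v1 <- numeric(mesh$ndof); a1 <- numeric(mesh$ndof)
  d1[fr] <- d1f
  a1[fr] <- (4 / dt^2) * (d1[fr] - d0[fr]) - (4 / dt) * v0[fr] - a0[fr]
  v1[fr] <- v0[fr] + dt / 2 * (a0[fr] + a1[fr])
  d1[cn] <- dc; v1[cn] <- vc; a1[cn] <- ac

  # transverse actuator reaction at the LE (row of the w-translation DOF)
  r_w <- sum(mesh$M[1, ] * a1) + sum(mesh$K[1, ] * d1) - f[1]
  rigid <- as.numeric(seq_len(mesh$ndof) %% 2 == 1)  # unit rigid translation
  out <- structure(list(d = d1, v = v1, a = a1, t = state$t + dt), class = "beam_state")
  attr(out, "reaction_force") <- r_w
  attr(out, "int_q") <- sum(rigid * f)
  attr(out, "int_mu_a") <- sum(rigid * (mesh$M %*% a1))
  out
}

#' Passive pitch angle from the trailing-edge displacement
#'
#' @param w_te trailing-edge transverse displacement, m.
#' @param zeta leading-edge position, m.
#' @param c chord, m.
#' @return pitch angle `atan((w_te - zeta) / c)` in radians.
#' @export
passive_pitch <- function(w_te, zeta, c) {
  if (any(c <= 0)) stop("chord must be positive")
  atan((w_te - zeta) / c)
}

#' First-harmonic characterisation of the passive pitch
#'
#' Least-squares fit of a pitch series to
#' `alpha(t) = pi/2 - alpha_a * cos(2 pi f t + phi)`, the first-harmonic
#' description used to summarise the passive rotation. The amplitude is
#' non-negative and the phase lies in (-pi, pi].
#'
#' @param alpha pitch series, rad.
#' @param t sampling times, s (uniform, covering at least one full period).
#' @param f flapping frequency, Hz.
#' @return list with `alpha_a` (rad) and `phi` (rad).
#' @export
first_harmonic_fit <- function(alpha, t, f) {
  stopifnot(length(alpha) == length(t), f > 0)
  if (diff(range(t)) < 1 / f - 1e-9) stop("series must cover at least one full period")
  if (length(t) < 4 || mean(diff(t)) > 1 / (3 * f)) {
    stop("need at least 3 samples per period")
  }
  y <- alpha - pi / 2
  X <- cbind(cos(2 * pi * f * t), sin(2 * pi * f * t))
  cf <- stats::lm.fit(X, y)$coefficients
  A <- cf[1]; B <- cf[2]
  alpha_a <- sqrt(A^2 + B^2)
  phi <- if (alpha_a < 1e-300) 0 else atan2(B, -A)
  if (phi <= -pi) phi <- phi + 2 * pi
  list(alpha_a = unname(alpha_a), phi = unname(phi))
}
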