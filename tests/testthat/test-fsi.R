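test_that("aitken_solve matches the monolithic solution of a linear system", {
  # d = A d + b, monolithic solution (I - A)^{-1} b
  A <- matrix(c(0.3, -0.5, 0.2, 0.4), 2, 2)
  b <- c(1, -2)
  g <- function(d) drop(A %*% d + b)
  d_star <- solve(diag(2) - A, b)
  sol <- aitken_solve(g, c(0, 0), tol = 1e-12, max_inner = 100)
  expect_equal(sol$d, d_star, tolerance = 1e-10)
})

test_that("Aitken relaxation converges where fixed under-relaxation diverges slowly", {
  # stiff added-mass-like map: plain iteration diverges (|A| > 1), fixed
  # under-relaxation contracts slowly, Aitken finds the optimal factor
  A <- diag(c(-1.8, -1.8))
  b <- c(1, 1)
  g <- function(d) drop(A %*% d + b)
  sa <- aitken_solve(g, c(0, 0), tol = 1e-10, max_inner = 100, relaxation = "aitken")
  sf <- aitken_solve(g, c(0, 0), tol = 1e-10, max_inner = 100,
                     omega0 = 0.5, relaxation = "fixed")
  expect_lt(sa$n_inner, sf$n_inner)
  # residual history shrinks overall
  rs <- sa$residuals
  expect_lt(rs[length(rs)], rs[1] * 1e-6)
})

test_that("aitken_solve reports the residual history on failure", {
  g <- function(d) 2 * d + 1   # divergent fixed point for plain iteration
  err <- tryCatch(aitken_solve(g, 0.3, tol = 1e-16, max_inner = 4,
                               relaxation = "fixed", omega0 = 1),
                  error = conditionMessage)
  expect_match(err, "did not converge")
  expect_match(err, "history")
})

test_that("partitioned coupled_step matches a monolithic added-mass solve to 1e-8", {
  # Load model linear in acceleration: q_j = -ca * w_ddot_j at each node.
  # Monolithic reference: Newmark on (M + ca*T*S) a + K d = r(bc), where T is
  # the consistent-load map from nodal q to the force vector and S picks the
  # w translations.
  w <- ref_wing()
  mesh <- beam_mesh(8, w$c, w$E_chord * w$I_chord, w$rho_w * w$hw)
  nn <- mesh$n_elements + 1
  ca <- pi / 4 * 1.2 * w$c    # added-mass line density scale
  # consistent-load map T (ndof x n_nodes)
  T <- vapply(seq_len(nn), function(j) {
    q <- numeric(nn); q[j] <- 1
    distributed_load_vector(mesh, q)
  }, numeric(mesh$ndof))
  S <- matrix(0, nn, mesh$ndof)
  S[cbind(seq_len(nn), mesh$w_dofs)] <- 1
  Ma <- ca * T %*% S

  kin <- kinematic_spec()
  dt <- 1 / (kin$f * 100)
  n_steps <- 25
  fr <- mesh$free; cn <- mesh$constrained

  # --- monolithic Newmark with augmented mass ---
  Mtot <- mesh$M + Ma
  m0 <- le_motion(kin, 0)
  d <- numeric(mesh$ndof); v <- numeric(mesh$ndof); a <- numeric(mesh$ndof)
  d[mesh$w_dofs] <- m0$zeta; v[mesh$w_dofs] <- m0$zeta_dot
  d[1] <- m0$zeta; v[1] <- m0$zeta_dot; a[1] <- m0$zeta_ddot
  a[fr] <- solve(Mtot[fr, fr],
                 -mesh$K[fr, fr] %*% d[fr] - mesh$K[fr, cn] %*% d[cn] -
                   Mtot[fr, cn] %*% a[cn])
  Keff <- mesh$K[fr, fr] + (4 / dt^2) * Mtot[fr, fr]
  for (i in seq_len(n_steps)) {
    m <- le_motion(kin, i * dt)
    dc <- c(m$zeta, 0); vc <- c(m$zeta_dot, 0); ac <- c(m$zeta_ddot, 0)
    rhs <- -mesh$K[fr, cn] %*% dc - Mtot[fr, cn] %*% ac +
      Mtot[fr, fr] %*% ((4 / dt^2) * d[fr] + (4 / dt) * v[fr] + a[fr])
    dnew <- solve(Keff, rhs)
    anew <- (4 / dt^2) * (dnew - d[fr]) - (4 / dt) * v[fr] - a[fr]
    vnew <- v[fr] + dt / 2 * (a[fr] + anew)
    d[fr] <- dnew; v[fr] <- vnew; a[fr] <- anew
    d[cn] <- dc; v[cn] <- vc; a[cn] <- ac
  }
  d_mono <- d

  # --- partitioned with the same load model as a provider ---
  provider <- list(
    eval = function(kin_n, t, dt) {
      q <- -ca * kin_n$w_ddot
      list(q = q, fx = 0 * q, fy = q, Fx = 0, Fy = NA_real_)
    },
    commit = function() invisible(NULL),
    mode = "oracle")
  state <- beam_state_init(mesh, bc = list(zeta = m0$zeta, zeta_dot = m0$zeta_dot,
                                           zeta_ddot = m0$zeta_ddot))
  # match the monolithic consistent initial acceleration
  state$a[fr] <- a0_part <- solve(Mtot[fr, fr],
                                  -mesh$K[fr, fr] %*% state$d[fr] -
                                    mesh$K[fr, cn] %*% state$d[cn] -
                                    Mtot[fr, cn] %*% c(m0$zeta_ddot, 0))
  op <- newmark_operator(mesh, dt)
  cfg <- coupling_config(tol_w = 1e-12, max_inner = 200)
  for (i in seq_len(n_steps)) {
    m <- le_motion(kin, i * dt)
    stp <- coupled_step(mesh, state, provider, dt,
                        bc = list(zeta = m$zeta, zeta_dot = m$zeta_dot,
                                  zeta_ddot = m$zeta_ddot),
                        cfg = cfg, op = op)
    state <- stp$state
  }
  expect_lt(max(abs(state$d - d_mono)) / max(abs(d_mono)), 1e-8)
})

test_that("coupling tolerance self-consistency: halving tol_w barely moves the mean lift", {
  base <- quick_run(n_cycles = 2, steps_per_cycle = 80,
                    coupling = coupling_config(tol_w = 1e-6))
  tight <- quick_run(n_cycles = 2, steps_per_cycle = 80,
                     coupling = coupling_config(tol_w = 5e-7))
  L1 <- cycle_average(base$series$t, base$series$L, 10, 2)
  L2 <- cycle_average(tight$series$t, tight$series$L, 10, 2)
  expect_lt(abs(L1 - L2) / abs(L2), 0.005)
})

test_that("run_cycles reports periodicity and inner-iteration statistics", {
  sol <- quick_run(n_cycles = 3, steps_per_cycle = 100)
  expect_s3_class(sol, "aeroelastic_solution")
  expect_true(is.finite(sol$periodicity))
  expect_lt(sol$periodicity, 0.05)
  expect_gt(sol$mean_inner, 1)
  expect_equal(nrow(sol$series), 3 * 100 + 1)
  expect_output(print(sol), "aeroelastic_solution")
  path <- tempfile(fileext = ".csv")
  write_solution_csv(sol, path)
  back <- read.csv(path)
  expect_equal(back$L, sol$series$L, tolerance = 1e-12)
})

test_that("coupling_config validates arguments", {
  expect_error(coupling_config(tol_w = 0))
  expect_error(coupling_config(omega0 = 0))
  expect_error(coupling_config(relaxation = "quadratic"))
})
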