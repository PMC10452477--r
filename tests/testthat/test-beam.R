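test_that("static tip-load deflection matches the cantilever closed form", {
  w <- ref_wing()
  EI <- w$E_chord * w$I_chord
  mesh <- beam_mesh(50, w$c, EI, w$rho_w * w$hw)
  F <- 1e-3
  sol <- static_solve(mesh, F, w$c)
  expect_equal(sol$w_at(w$c), F * w$c^3 / (3 * EI), tolerance = 1e-3)
})

test_that("static mid-span load matches the closed form", {
  EI <- 2.5; L <- 0.8; F <- 0.4; a <- L / 2
  mesh <- beam_mesh(50, L, EI, 1)
  sol <- static_solve(mesh, F, a)
  expect_equal(sol$w_at(L), F * a^2 * (3 * L - a) / (6 * EI), tolerance = 1e-3)
  expect_equal(static_solve(mesh, 0, a)$w, rep(0, 51))
})

test_that("consistent load vectors integrate exactly", {
  mesh <- beam_mesh(8, 1, 1, 1)
  # uniform distributed load: total force and element pattern
  q0 <- 3.7
  f <- distributed_load_vector(mesh, rep(q0, 9))
  rigid <- as.numeric(seq_len(mesh$ndof) %% 2 == 1)
  expect_equal(sum(rigid * f), q0 * 1)      # total transverse force
  fp <- point_load_vector(mesh, 2.5, 0.37)
  expect_equal(sum(rigid * fp), 2.5)
  expect_error(distributed_load_vector(mesh, rep(1, 5)))
})

test_that("natural frequencies converge to the analytic cantilever values", {
  EI <- 2.0; L <- 0.7; mu_m <- 0.5
  mesh <- beam_mesh(100, L, EI, mu_m)
  fn <- beam_natural_frequencies(mesh, 3)
  fex <- analytic_cantilever_freqs(EI, mu_m, L, 3)
  expect_equal(fn, fex, tolerance = 1e-5)
  # O(h^2) convergence of the first eigenfrequency
  err <- vapply(c(4, 8, 16), function(n) {
    abs(beam_natural_frequencies(beam_mesh(n, L, EI, mu_m), 1) - fex[1])
  }, numeric(1))
  # each refinement should cut the error by close to 4 (allow slack)
  expect_true(all(err[-3] / err[-1] > 3))
})

test_that("Newmark free vibration conserves energy over 100 periods", {
  EI <- 1.0; L <- 0.5; mu_m <- 0.8
  mesh <- beam_mesh(12, L, EI, mu_m)
  f1 <- beam_natural_frequencies(mesh, 1)
  # initial condition: static tip-load shape, zero velocity, LE fixed
  d0 <- static_solve(mesh, 1, L)$d
  state <- structure(list(d = d0, v = numeric(mesh$ndof), a = numeric(mesh$ndof), t = 0),
                     class = "beam_state")
  fr <- mesh$free
  rhs <- -mesh$K[fr, fr] %*% d0[fr]
  state$a[fr] <- solve(mesh$M[fr, fr], rhs)
  energy <- function(s) {
    0.5 * sum(s$v * (mesh$M %*% s$v)) + 0.5 * sum(s$d * (mesh$K %*% s$d))
  }
  e0 <- energy(state)
  dt <- 1 / (f1 * 40)
  bc <- list(zeta = 0, zeta_dot = 0, zeta_ddot = 0)
  op <- newmark_operator(mesh, dt)
  for (i in seq_len(4000)) {  # 100 periods at 40 steps/period
    state <- step_dynamic(mesh, state, rep(0, mesh$n_elements + 1), dt, bc, op)
  }
  expect_equal(energy(state), e0, tolerance = 1e-3)
})

test_that("rigid limit: very stiff beam follows the base motion, pitch -> 0", {
  w <- ref_wing(E_chord = 0.3e15)  # 1e6 x stiffer
  sol <- quick_run(wing = w, n_cycles = 2, steps_per_cycle = 100)
  s <- sol$series
  expect_lt(max(abs(s$w_te - s$zeta)), 1e-6 * w$c)
  expect_lt(max(abs(s$alpha)), 1e-6)
})

test_that("quasi-static base excitation transmits the base amplitude", {
  # f << f1: tip amplitude ~ base amplitude
  EI <- 5; L <- 0.3; mu_m <- 0.6
  mesh <- beam_mesh(10, L, EI, mu_m)
  f1 <- beam_natural_frequencies(mesh, 1)
  f <- f1 / 50
  za <- 1e-3
  dt <- 1 / (f * 200)
  op <- newmark_operator(mesh, dt)
  state <- beam_state_init(mesh, bc = list(zeta = za, zeta_dot = 0,
                                           zeta_ddot = -(2 * pi * f)^2 * za))
  tip <- numeric(600)
  q0 <- rep(0, mesh$n_elements + 1)
  for (i in seq_len(600)) {  # 3 periods
    t1 <- i * dt
    bc <- list(zeta = za * cos(2 * pi * f * t1),
               zeta_dot = -2 * pi * f * za * sin(2 * pi * f * t1),
               zeta_ddot = -(2 * pi * f)^2 * za * cos(2 * pi * f * t1))
    state <- step_dynamic(mesh, state, q0, dt, bc, op)
    tip[i] <- state$d[mesh$ndof - 1]
  }
  last <- tip[401:600]
  expect_equal((max(last) - min(last)) / 2, za, tolerance = 0.02)
})

test_that("passive pitch geometry identities hold", {
  expect_equal(passive_pitch(0.5, 0.5, 0.029), 0)
  expect_equal(passive_pitch(0.029, 0, 0.029), pi / 4)
  expect_equal(passive_pitch(-0.029 * tan(0.2), 0, 0.029), -0.2)
  expect_error(passive_pitch(0, 0, -1), "positive")
})

test_that("first-harmonic fit recovers amplitude and phase", {
  f <- 10
  # uniform grid over exactly two periods without the duplicate endpoint,
  # so the discrete harmonics are orthogonal
  t <- seq(0, 2 / f, length.out = 201)[-201]
  alpha <- pi / 2 - 0.5 * cos(2 * pi * f * t + 0.3)
  fit <- first_harmonic_fit(alpha, t, f)
  expect_equal(fit$alpha_a, 0.5, tolerance = 1e-12)
  expect_equal(fit$phi, 0.3, tolerance = 1e-12)
  # orthogonality: a 3rd harmonic does not bias the fundamental
  alpha3 <- alpha + 0.1 * cos(3 * 2 * pi * f * t + 1.1)
  fit3 <- first_harmonic_fit(alpha3, t, f)
  expect_equal(fit3$alpha_a, 0.5, tolerance = 1e-6)
  expect_equal(fit3$phi, 0.3, tolerance = 1e-6)
  # constant pi/2 -> zero amplitude
  fit0 <- first_harmonic_fit(rep(pi / 2, length(t)), t, f)
  expect_equal(fit0$alpha_a, 0)
  expect_error(first_harmonic_fit(alpha[1:5], t[1:5], f), "period")
})

test_that("dynamic stepping validates dt", {
  mesh <- beam_mesh(4, 1, 1, 1)
  state <- beam_state_init(mesh)
  expect_error(step_dynamic(mesh, state, rep(0, 5), 0, list(zeta = 0, zeta_dot = 0, zeta_ddot = 0)),
               "dt")
  expect_error(newmark_operator(mesh, -1), "dt")
})
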