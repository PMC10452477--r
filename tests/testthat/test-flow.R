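test_that("Taylor-Green kinetic energy decays as exp(-4 nu t)", {
  nu <- 0.02
  s <- spectral_flow_init(48, nu, function(X, Y) 2 * cos(X) * cos(Y))
  ke0 <- spectral_kinetic_energy(s)
  s <- spectral_flow_step(s, dt = 0.01, n_steps = 100)
  expect_equal(spectral_kinetic_energy(s) / ke0, exp(-4 * nu * 1.0),
               tolerance = 1e-6)
})

test_that("spectral vorticity stays real and conserves the zero mean", {
  s <- spectral_flow_init(32, 0.05, function(X, Y) sin(2 * X) * cos(Y))
  s <- spectral_flow_step(s, dt = 0.01, n_steps = 50)
  om <- Re(stats::fft(s$omega_hat, inverse = TRUE)) / s$n^2
  expect_lt(abs(mean(om)), 1e-12)
  vel <- spectral_flow_velocity(s)
  expect_true(all(is.finite(vel$u)))
})

test_that("IB solver preserves a uniform freestream under marker motion", {
  s <- ib_flow_init(32, 32, 0.1, 0.1, rho = 1.2, mu = 1.8e-5, uinf = c(1, 0.3))
  mk <- list(x = seq(0.03, 0.06, length.out = 8), y = rep(0.05, 8),
             u = rep(1, 8), v = rep(0.3, 8), ds = rep(0.03 / 7, 8))
  for (i in 1:20) {
    mk$y <- 0.05 + 0.001 * sin(i / 3)   # markers advect with the stream
    s <- ib_flow_step(s, 2e-4, markers = mk)
  }
  expect_lt(max(abs(s$u - 1)), 1e-10)
  expect_lt(max(abs(s$v - 0.3)), 1e-10)
  expect_lt(ib_divergence(s), 1e-10)
})

test_that("projection drives the discrete divergence to round-off", {
  s <- ib_flow_init(24, 24, 0.06, 0.06, rho = 1.0, mu = 2e-5, uinf = c(0.8, 0))
  mk <- list(x = seq(0.02, 0.04, length.out = 6), y = rep(0.03, 6),
             u = rep(0, 6), v = rep(0, 6), ds = rep(0.02 / 5, 6))
  for (i in 1:30) s <- ib_flow_step(s, ib_stable_dt(s), markers = mk)
  expect_lt(ib_divergence(s), 1e-9)
})

test_that("a plate aligned with the stream has zero lift and positive drag", {
  cc <- 0.029
  s <- ib_flow_init(64, 48, 6 * cc, 4 * cc, x0 = -2 * cc, y0 = -2 * cc,
                    rho = 1.2, mu = 1.81e-5, uinf = c(1, 0))
  mk <- list(x = seq(0, cc, length.out = 16), y = rep(0, 16),
             u = rep(0, 16), v = rep(0, 16), ds = rep(cc / 15, 16))
  for (i in 1:150) s <- ib_flow_step(s, ib_stable_dt(s), markers = mk)
  bf <- attr(s, "body_force")
  q <- 0.5 * 1.2 * 1^2 * cc
  expect_gt(bf[["fx"]] / q, 0)            # drag
  expect_lt(abs(bf[["fy"]]) / q, 0.01)    # symmetric: no lift
})

test_that("stable time step shrinks with finer grids and faster flow", {
  s1 <- ib_flow_init(16, 16, 0.1, 0.1, uinf = c(1, 0))
  s2 <- ib_flow_init(32, 32, 0.1, 0.1, uinf = c(1, 0))
  s3 <- ib_flow_init(16, 16, 0.1, 0.1, uinf = c(4, 0))
  expect_gt(ib_stable_dt(s1), ib_stable_dt(s2))
  expect_gt(ib_stable_dt(s1), ib_stable_dt(s3))
  expect_error(ib_flow_step(s1, dt = 0), "dt")
})

test_that("compute_loads integrates a uniform pressure to the closed-surface identity", {
  # closed circle under constant pressure: zero net force
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  r <- 0.5
  surf <- data.frame(x = r * cos(th), y = r * sin(th),
                     nx = cos(th), ny = sin(th),
                     ds = rep(2 * pi * r / 100, 100))
  ld <- compute_loads(surf, function(x, y) rep(3.2, length(x)))
  expect_equal(ld$Fx, 0, tolerance = 1e-12)
  expect_equal(ld$Fy, 0, tolerance = 1e-12)
  # linear pressure field p = x: buoyancy-like net force -A in x
  ld2 <- compute_loads(surf, function(x, y) x)
  expect_equal(ld2$Fx, -pi * r^2, tolerance = 1e-3)
  expect_equal(ld2$Fy, 0, tolerance = 1e-12)
})

test_that("compute_loads adds the Couette shear traction", {
  # u = gamma * y: traction on a y-normal wall is mu*gamma in x
  mu <- 1.8e-5; gam <- 50
  surf <- data.frame(x = seq(0, 1, length.out = 11), y = 0,
                     nx = 0, ny = 1, ds = 0.1)
  ld <- compute_loads(surf,
                      p_fun = function(x, y) rep(0, length(x)),
                      gradu_fun = function(x, y) {
                        list(ux = rep(0, length(x)), uy = rep(gam, length(x)),
                             vx = rep(0, length(x)), vy = rep(0, length(x)))
                      }, mu = mu)
  expect_equal(ld$stations$fx, rep(mu * gam, 11))
  expect_equal(ld$Fy, 0)
  expect_error(compute_loads(surf[, -3], function(x, y) 0), "columns")
  bad <- surf; bad$ds[3] <- 0
  expect_error(compute_loads(bad, function(x, y) 0), "degenerate")
  bad2 <- surf; bad2$ny <- 2
  expect_error(compute_loads(bad2, function(x, y) 0), "unit")
})

test_that("RBF deformation reproduces linear fields exactly and pins the boundary", {
  set.seed(4)
  control <- cbind(runif(12), runif(12))
  nodes <- cbind(runif(40), runif(40))
  # affine displacement field: must be reproduced exactly everywhere
  A <- matrix(c(0.01, -0.02, 0.03, 0.015), 2, 2)
  b <- c(0.1, -0.05)
  disp <- t(A %*% t(control)) + matrix(b, 12, 2, byrow = TRUE)
  out <- rbf_deform(nodes, control, disp)
  exact <- nodes + t(A %*% t(nodes)) + matrix(b, 40, 2, byrow = TRUE)
  expect_equal(out, exact, tolerance = 1e-9)
  # interpolation: control points move exactly as prescribed
  out_c <- rbf_deform(control, control, disp)
  expect_equal(out_c, control + disp, tolerance = 1e-9)
})

test_that("deform_mesh moves the surface, pins the outer boundary, flags inversion", {
  gx <- seq(0, 1, length.out = 6)
  nodes <- as.matrix(expand.grid(x = gx, y = gx))
  outer_idx <- which(nodes[, 1] %in% c(0, 1) | nodes[, 2] %in% c(0, 1))
  surf_idx <- which(abs(nodes[, 1] - 0.4) < 1e-9 & nodes[, 2] > 0.3 & nodes[, 2] < 0.9)
  mesh <- list(nodes = nodes, surface = surf_idx, outer = outer_idx)
  dzy <- cbind(rep(0, length(surf_idx)), rep(0.02, length(surf_idx)))
  m2 <- deform_mesh(mesh, dzy)
  expect_equal(m2$nodes[outer_idx, ], nodes[outer_idx, ], tolerance = 1e-9)
  expect_equal(m2$nodes[surf_idx, 2] - nodes[surf_idx, 2],
               rep(0.02, length(surf_idx)), tolerance = 1e-9)
  # an absurd displacement inverts cells when connectivity is supplied
  quads <- t(vapply(seq_len(5 * 5), function(k) {
    i <- (k - 1) %% 5 + 1; j <- (k - 1) %/% 5 + 1
    n <- function(i, j) (j - 1) * 6 + i
    c(n(i, j), n(i + 1, j), n(i + 1, j + 1), n(i, j + 1))
  }, numeric(4)))
  mesh$quads <- quads
  big <- cbind(rep(0.5, length(surf_idx)), rep(0, length(surf_idx)))
  expect_error(deform_mesh(mesh, big), "inverted")
})

test_that("VTK snapshots are well-formed ASCII", {
  s <- ib_flow_init(16, 12, 0.1, 0.075, uinf = c(1, 0))
  path <- tempfile(fileext = ".vtk")
  write_vtk_snapshot(s, path, v_ref = 1)
  lines <- readLines(path)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("DIMENSIONS 16 12 1", lines)))
  expect_true(any(grepl("VECTORS velocity double", lines)))
  expect_true(any(grepl("pressure_normalized", lines)))
  expect_equal(sum(grepl("LOOKUP_TABLE default", lines)), 2)
})
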