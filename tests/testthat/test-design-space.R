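test_that("design-space sampling covers the ranges in both modes", {
  rng <- list(rho_air = c(0.91, 1.2), beta = c(0, 1), V = c(0.5, 1.5))
  g <- sample_design_space(rng, 3, "grid")
  expect_equal(nrow(g), 27)
  expect_equal(range(g$rho_air), rng$rho_air)
  expect_equal(range(g$V), rng$V)
  l <- sample_design_space(rng, 3, "latin", seed = 9)
  expect_equal(nrow(l), 27)
  expect_true(all(l$beta >= 0 & l$beta <= 1))
  l2 <- sample_design_space(rng, 3, "latin", seed = 9)
  expect_identical(l, l2)
  expect_error(sample_design_space(list(rho_air = 1, beta = c(0, 1), V = c(0.5, 1.5)), 3),
               "rho_air")
})

test_that("surrogate training is seeded-deterministic and fits a smooth response", {
  set.seed(11)
  n <- 80
  pts <- data.frame(rho_air = runif(n, 0.9, 1.2), beta = runif(n, 0, 1),
                    V = runif(n, 0.5, 1.5))
  pts$L <- 1e-3 * (2 * pts$rho_air * pts$V^2 * sin(pts$beta) + 0.3 * pts$V)
  m1 <- train_surrogate(pts, outputs = "L", seed = 5)
  m2 <- train_surrogate(pts, outputs = "L", seed = 5)
  expect_identical(m1$net$wts, m2$net$wts)
  expect_lt(m1$train_rmse[["L"]], 0.02 * stats::sd(pts$L))
  pred <- predict(m1, pts[1:10, ])
  expect_equal(pred$L, pts$L[1:10], tolerance = 0.05)
  expect_warning(train_surrogate(pts[1:20, ], outputs = "L"), "shrunk")
  expect_output(print(m1), "surrogate_model")
})

test_that("surrogate serialisation captures architecture and weights", {
  set.seed(2)
  pts <- data.frame(rho_air = runif(70, 0.9, 1.2), beta = runif(70, 0, 1),
                    V = runif(70, 0.5, 1.5))
  pts$L <- pts$rho_air + pts$V
  m <- train_surrogate(pts, outputs = "L", seed = 1, size = 10)
  path <- tempfile(fileext = ".json")
  write_surrogate(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$size, 10)
  expect_equal(back$wts, m$net$wts, tolerance = 1e-12)
  expect_equal(unlist(back$x_mu), m$x_mu, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("Re polynomial recovery is exact on noiseless data", {
  co <- c(2600, -0.9, 8e-5)
  h <- seq(0, 3000, length.out = 15)
  obs <- data.frame(h = h, Re = co[1] + co[2] * h + co[3] * h^2)
  fit <- fit_re_polynomial(obs, degree = 2)
  expect_equal(fit$coefficients, co, tolerance = 1e-9)
  expect_equal(fit$predict(1234), co[1] + co[2] * 1234 + co[3] * 1234^2,
               tolerance = 1e-9)
  expect_error(fit_re_polynomial(obs[1:2, ], degree = 2), "distinct")
})

test_that("equilibrium selection finds the analytic optimum of a known surrogate", {
  # stand-in "surrogate" with an exact analytic response L = k rho V^2 sin(beta)
  k <- 1.5e-2
  .S3method("predict", "test_surrogate",
            function(object, newdata, ...) {
              data.frame(L = k * newdata$rho_air * newdata$V^2 * sin(newdata$beta))
            })
  fake2 <- structure(list(outputs = "L"), class = "test_surrogate")
  obs <- gen_flight_observations(seq(193, 3000, length.out = 12), seed = 1, noise_sd = 0)
  re_fit <- fit_re_polynomial(obs)
  crit <- equilibrium_criteria(re_fit = re_fit)
  branch <- select_equilibrium(fake2, crit, c(193, 3000))
  expect_equal(nrow(branch), 2)
  expect_true(all(branch$feasible))
  # selected points satisfy both constraints
  expect_true(all(abs(branch$L - 5e-3) <= 1e-4))
  Re_t <- re_fit$predict(branch$h)
  expect_true(all(abs(branch$Re - Re_t) / Re_t <= 0.10))
})

test_that("equilibrium selection errors when infeasible everywhere", {
  .S3method("predict", "hopeless_surrogate",
            function(object, newdata, ...) data.frame(L = rep(1, nrow(newdata))))
  hopeless <- structure(list(outputs = "L"), class = "hopeless_surrogate")
  obs <- gen_flight_observations(c(193, 1500, 3000), seed = 1, noise_sd = 0)
  crit <- equilibrium_criteria(re_fit = fit_re_polynomial(obs))
  expect_error(select_equilibrium(hopeless, crit, c(193, 3000), n_grid = 11),
               "no equilibrium")
})
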