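#' Sample the (air density, stroke plane angle, flight speed) design space
#'
#' @param ranges named list of length-2 ranges for `rho_air` (kg/m^3),
#'   `beta` (rad) and `V` (m/s).
#' @param n_per_axis points per axis (grid mode) or total points =
#'   `n_per_axis^3` (latin mode).
#' @param mode `"grid"` (corners included) or `"latin"` (seeded maximin-free
#'   latin hypercube).
#' @param seed RNG seed for latin sampling.
#' @return data.frame with columns `rho_air`, `beta`, `V`.
#' @export
sample_design_space <- function(ranges = list(rho_air = c(0.91, 1.2),
                                              beta = c(0, 60 * pi / 180),
                                              V = c(0.5, 1.5)),
                                n_per_axis = 5, mode = c("grid", "latin"),
                                seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n_per_axis >= 2)
  for (nm in c("rho_air", "beta", "V")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || diff(r) < 0) stop("bad range for ", nm)
  }
  scale1 <- function(u, r) r[1] + u * (r[2] - r[1])
  if (mode == "grid") {
    g <- expand.grid(rho_air = seq(ranges$rho_air[1], ranges$rho_air[2], length.out = n_per_axis),
                     beta = seq(ranges$beta[1], ranges$beta[2], length.out = n_per_axis),
                     V = seq(ranges$V[1], ranges$V[2], length.out = n_per_axis))
    return(unique(g))
  }
  set.seed(seed)
  U <- lhs::randomLHS(n_per_axis^3, 3)
  data.frame(rho_air = scale1(U[, 1], ranges$rho_air),
             beta = scale1(U[, 2], ranges$beta),
             V = scale1(U[, 3], ranges$V))
}

#' Evaluate design points with the coupled solver
#'
#' Runs one aeroelastic simulation per design point (oracle mode by default)
#' and reduces each to its cycle-averaged performance.
#'
#' @param points data.frame from [sample_design_space()].
#' @param wing a [wing_spec()].
#' @param zeta_a,f plunge amplitude (m) and frequency (Hz).
#' @param mode,n_elements,steps_per_cycle,n_cycles forwarded to [run_cycles()].
#' @param mu dynamic viscosity, Pa s.
#' @return `points` with appended output columns `L`, `Th`, `P`, `Paero`,
#'   `Pinertial`, `eta`, `alpha_eff`, `CL`, `CT`, `Re`.
#' @export
evaluate_design_points <- function(points, wing = wing_spec(),
                                   zeta_a = 31e-3, f = 10,
                                   mode = "oracle", n_elements = 12,
                                   steps_per_cycle = 160, n_cycles = 3,
                                   mu = isa_constants$mu) {
  out <- lapply(seq_len(nrow(points)), function(i) {
    kin <- kinematic_spec(zeta_a = zeta_a, f = f, beta = points$beta[i])
    fl <- flight_condition(rho_air = points$rho_air[i], V = points$V[i],
                           mu = mu, c = wing$c)
    sol <- run_cycles(wing, kin, fl, n_cycles = n_cycles, mode = mode,
                      n_elements = n_elements, steps_per_cycle = steps_per_cycle)
    pf <- cycle_performance(sol, fl, cycle_index = n_cycles)
    c(L = pf$L_bar, Th = pf$T_bar, P = pf$P_bar, Paero = pf$Paero_bar,
      Pinertial = pf$Pinertial_bar, eta = pf$eta, alpha_eff = pf$alpha_eff_bar,
      CL = pf$CL_bar, CT = pf$CT_bar, Re = fl$Re)
  })
  cbind(points, as.data.frame(do.call(rbind, out)))
}

#' Train a multilayer-perceptron surrogate of the design-space outputs
#'
#' Single sigmoid hidden layer (45 units by default) with linear outputs,
#' trained on standardised inputs and outputs by regularised least squares
#' (weight decay), seeded for bitwise-reproducible weights. With fewer than
#' 60 training points the hidden layer is shrunk (with a warning) to keep the
#' problem over-determined.
#'
#' @param points evaluated design points ([evaluate_design_points()]).
#' @param outputs output column names to model.
#' @param seed RNG seed for the initial weights.
#' @param size hidden-layer width.
#' @param decay L2 weight-decay coefficient.
#' @param maxit optimiser iteration cap.
#' @return object of class `surrogate_model` with a [predict][predict.surrogate_model]
#'   method; `train_rmse` holds the per-output training RMSE (original units).
#' @export
train_surrogate <- function(points,
                            outputs = c("L", "Th", "P", "Paero", "Pinertial",
                                        "eta", "alpha_eff", "CL", "CT"),
                            seed = 1, size = 45, decay = 1e-4, maxit = 1500) {
  inputs <- c("rho_air", "beta", "V")
  stopifnot(all(inputs %in% names(points)))
  outputs <- intersect(outputs, names(points))
  X <- as.matrix(points[, inputs])
  Y <- as.matrix(points[, outputs, drop = FALSE])
  if (any(!is.finite(X)) || any(!is.finite(Y))) stop("non-finite training data")
  n <- nrow(X)
  if (n < 60 && size > floor(n / 2)) {
    size <- max(2L, floor(n / 2))
    warning(sprintf("only %d training points: hidden layer shrunk to %d units", n, size))
  }
  x_mu <- colMeans(X); x_sd <- apply(X, 2, stats::sd); x_sd[x_sd == 0] <- 1
  y_mu <- colMeans(Y); y_sd <- apply(Y, 2, stats::sd); y_sd[y_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  Ys <- sweep(sweep(Y, 2, y_mu), 2, y_sd, "/")
  set.seed(seed)
  net <- nnet::nnet(Xs, Ys, size = size, linout = TRUE, decay = decay,
                    maxit = maxit, trace = FALSE, MaxNWts = 100000)
  pred_s <- matrix(stats::predict(net, Xs), n, length(outputs))
  resid <- sweep(pred_s - Ys, 2, y_sd, "*")
  model <- structure(
    list(net = net, inputs = inputs, outputs = outputs,
         x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
         seed = seed, size = size, decay = decay, maxit = maxit,
         train_rmse = sqrt(colMeans(resid^2))),
    class = "surrogate_model"
  )
  model
}

#' Predict design-space outputs from a trained surrogate
#'
#' @param object a [train_surrogate()] model.
#' @param newdata data.frame with columns `rho_air`, `beta`, `V`.
#' @param ... unused.
#' @return data.frame of predicted outputs in original units.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$inputs])
  Xs <- sweep(sweep(X, 2, object$x_mu), 2, object$x_sd, "/")
  P <- matrix(stats::predict(object$net, Xs), nrow(X), length(object$outputs))
  P <- sweep(sweep(P, 2, object$y_sd, "*"), 2, object$y_mu, "+")
  colnames(P) <- object$outputs
  as.data.frame(P)
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("surrogate_model: %d sigmoid units, decay = %g, seed = %d\n",
              x$size, x$decay, x$seed))
  cat("  outputs:", paste(x$outputs, collapse = ", "), "\n")
  cat("  train RMSE:", paste(sprintf("%s=%.3g", x$outputs, x$train_rmse), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a surrogate to JSON (architecture, scaling, weights)
#'
#' @param model a [train_surrogate()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  jsonlite::write_json(
    list(inputs = model$inputs, outputs = model$outputs,
         size = model$size, decay = model$decay, seed = model$seed,
         x_mu = model$x_mu, x_sd = model$x_sd,
         y_mu = model$y_mu, y_sd = model$y_sd,
         n = model$net$n, wts = model$net$wts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Least-squares polynomial fit of Reynolds number versus altitude
#'
#' @param observations data.frame with columns `h` (m) and `Re`.
#' @param degree polynomial degree (default 2).
#' @return object of class `re_polynomial`: coefficients (ascending powers)
#'   and a `predict` function of altitude.
#' @export
fit_re_polynomial <- function(observations, degree = 2) {
  stopifnot(all(c("h", "Re") %in% names(observations)))
  h <- observations$h; Re <- observations$Re
  if (length(unique(h)) < degree + 1) {
    stop(sprintf("need at least %d distinct altitudes for degree %d", degree + 1, degree))
  }
  X <- outer(h, 0:degree, "^")
  qr_X <- qr(X)
  if (qr_X$rank < degree + 1) stop("rank-deficient polynomial design")
  coefs <- qr.coef(qr_X, Re)
  structure(
    list(coefficients = unname(coefs), degree = degree,
         predict = function(hh) drop(outer(hh, 0:degree, "^") %*% coefs)),
    class = "re_polynomial"
  )
}

#' Equilibrium-flight selection criteria
#'
#' A design point is an equilibrium-aerodynamically realizable flight when
#' its predicted mean lift balances the body weight within tolerance and its
#' Reynolds number matches the observed altitude trend within a relative
#' tolerance.
#'
#' @param L_target target mean lift (body weight), N.
#' @param L_tol lift tolerance, N.
#' @param re_fit a [fit_re_polynomial()] object.
#' @param re_tol relative Reynolds tolerance.
#' @return object of class `equilibrium_criteria`.
#' @export
equilibrium_criteria <- function(L_target = 5e-3, L_tol = 1e-4, re_fit,
                                 re_tol = 0.10) {
  stopifnot(L_tol > 0, re_tol > 0, inherits(re_fit, "re_polynomial"))
  structure(list(L_target = L_target, L_tol = L_tol,
                 re_fit = re_fit, re_tol = re_tol),
            class = "equilibrium_criteria")
}

#' Select the equilibrium flight branch across altitude
#'
#' For each altitude the air density is fixed by the standard atmosphere and
#' a dense (beta, V) grid of surrogate predictions is screened for
#' feasibility (`|L - L_target| <= L_tol` and `|Re - Re_fit(h)| / Re_fit(h)
#' <= re_tol`); among feasible points the one minimising `|L - L_target|` is
#' selected (ties broken toward the smaller Reynolds mismatch) and then
#' refined on a local sub-grid. Altitudes with no feasible point are flagged
#' with `feasible = FALSE`.
#'
#' @param surrogate a [train_surrogate()] model.
#' @param criteria an [equilibrium_criteria()].
#' @param altitude_grid altitudes, m.
#' @param beta_range,V_range search ranges (rad, m/s).
#' @param n_grid grid resolution per axis.
#' @param c_ref chord for the Reynolds number, m.
#' @param mu dynamic viscosity, Pa s.
#' @return data.frame (one row per altitude): `h`, `rho_air`, `beta`, `V`,
#'   `Re`, the surrogate outputs, and `feasible`.
#' @export
select_equilibrium <- function(surrogate, criteria, altitude_grid,
                               beta_range = c(0, 60 * pi / 180),
                               V_range = c(0.5, 1.5), n_grid = 101,
                               c_ref = 2.9e-2, mu = isa_constants$mu) {
  pick <- function(rho, h, b_rng, v_rng, n) {
    grid <- expand.grid(beta = seq(b_rng[1], b_rng[2], length.out = n),
                        V = seq(v_rng[1], v_rng[2], length.out = n))
    grid$rho_air <- rho
    pred <- predict(surrogate, grid)
    Re <- rho * grid$V * c_ref / mu
    Re_target <- criteria$re_fit$predict(h)
    dL <- abs(pred$L - criteria$L_target)
    dRe <- abs(Re - Re_target) / Re_target
    ok <- dL <= criteria$L_tol & dRe <= criteria$re_tol
    if (!any(ok)) return(NULL)
    cand <- which(ok)
    best <- cand[order(dL[cand], dRe[cand])][1]
    list(beta = grid$beta[best], V = grid$V[best], Re = Re[best],
         pred = pred[best, , drop = FALSE])
  }
  rows <- lapply(altitude_grid, function(h) {
    rho <- density_at_altitude(h)
    sel <- pick(rho, h, beta_range, V_range, n_grid)
    if (!is.null(sel)) {
      # local refinement around the coarse optimum
      db <- diff(beta_range) / (n_grid - 1)
      dv <- diff(V_range) / (n_grid - 1)
      sel2 <- pick(rho, h,
                   pmax(pmin(c(sel$beta - db, sel$beta + db), beta_range[2]), beta_range[1]),
                   pmax(pmin(c(sel$V - dv, sel$V + dv), V_range[2]), V_range[1]), 21)
      if (!is.null(sel2)) sel <- sel2
      cbind(data.frame(h = h, rho_air = rho, beta = sel$beta, V = sel$V,
                       Re = sel$Re, feasible = TRUE), sel$pred)
    } else {
      out <- data.frame(h = h, rho_air = rho, beta = NA_real_, V = NA_real_,
                        Re = NA_real_, feasible = FALSE)
      for (nm in surrogate$outputs) out[[nm]] <- NA_real_
      out
    }
  })
  branch <- do.call(rbind, rows)
  if (!any(branch$feasible)) {
    stop("no equilibrium-aerodynamically realizable flight found at any altitude")
  }
  branch
}
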