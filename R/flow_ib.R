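#' Cartesian immersed-boundary Navier-Stokes solver
#'
#' Projection (fractional-step) solver for the 2D laminar incompressible
#' Navier-Stokes equations on a staggered MAC grid, with a direct-forcing
#' immersed boundary representing the moving, deforming plate. Inflow
#' (Dirichlet freestream) on the left, far-field Dirichlet top and bottom,
#' zero-gradient outflow on the right. The pressure Poisson equation is
#' solved with a pre-factorised sparse Cholesky decomposition, so the
#' discrete divergence after projection is at round-off level.
#'
#' @param nx,ny cells in x and y.
#' @param Lx,Ly domain size, m.
#' @param x0,y0 lower-left corner, m.
#' @param rho fluid density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param uinf freestream velocity, length-2 (m/s).
#' @return object of class `ib_flow_state` with staggered fields `u`
#'   (`(nx+1) x ny`), `v` (`nx x (ny+1)`), `p` (`nx x ny`), initialised to
#'   the freestream.
#' @export
ib_flow_init <- function(nx, ny, Lx, Ly, x0 = 0, y0 = 0,
                         rho = 1.2, mu = 1.81e-5, uinf = c(1, 0)) {
  stopifnot(nx >= 8, ny >= 8, Lx > 0, Ly > 0, rho > 0, mu > 0)
  dx <- Lx / nx; dy <- Ly / ny
  s <- list(nx = nx, ny = ny, Lx = Lx, Ly = Ly, x0 = x0, y0 = y0,
            dx = dx, dy = dy, rho = rho, mu = mu, uinf = uinf, t = 0,
            u = matrix(uinf[1], nx + 1, ny),
            v = matrix(uinf[2], nx, ny + 1),
            p = matrix(0, nx, ny))
  s$poisson <- .ib_poisson_factor(nx, ny, dx, dy)
  class(s) <- "ib_flow_state"
  s
}

# 5-point pressure Laplacian: Neumann on left/top/bottom (prescribed-velocity
# boundaries), Dirichlet p = 0 on the outflow (right) boundary.
.ib_poisson_factor <- function(nx, ny, dx, dy) {
  idx <- function(i, j) (j - 1) * nx + i
  n <- nx * ny
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, val) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, val)
  }
  cx <- 1 / dx^2; cy <- 1 / dy^2
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- idx(i, j)
      diag <- 0
      if (i > 1) { add(k, idx(i - 1, j), -cx); diag <- diag + cx }
      if (i < nx) { add(k, idx(i + 1, j), -cx); diag <- diag + cx }
      else diag <- diag + 2 * cx  # ghost p = -p across the outflow (p = 0 face)
      if (j > 1) { add(k, idx(i, j - 1), -cy); diag <- diag + cy }
      if (j < ny) { add(k, idx(i, j + 1), -cy); diag <- diag + cy }
      add(k, k, diag)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
}

# bilinear interpolation of a field given its node origin and spacing
.ib_interp <- function(F, ox, oy, dx, dy, xs, ys) {
  nx <- nrow(F); ny <- ncol(F)
  gx <- (xs - ox) / dx + 1
  gy <- (ys - oy) / dy + 1
  i0 <- pmin(pmax(floor(gx), 1), nx - 1)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1)
  fx <- pmin(pmax(gx - i0, 0), 1)
  fy <- pmin(pmax(gy - j0, 0), 1)
  F[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    F[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    F[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    F[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# spread values onto a field with the transpose of bilinear interpolation
.ib_spread <- function(F, ox, oy, dx, dy, xs, ys, vals) {
  nx <- nrow(F); ny <- ncol(F)
  gx <- (xs - ox) / dx + 1
  gy <- (ys - oy) / dy + 1
  i0 <- pmin(pmax(floor(gx), 1), nx - 1)
  j0 <- pmin(pmax(floor(gy), 1), ny - 1)
  fx <- pmin(pmax(gx - i0, 0), 1)
  fy <- pmin(pmax(gy - j0, 0), 1)
  for (k in seq_along(xs)) {
    F[i0[k], j0[k]] <- F[i0[k], j0[k]] + vals[k] * (1 - fx[k]) * (1 - fy[k])
    F[i0[k] + 1, j0[k]] <- F[i0[k] + 1, j0[k]] + vals[k] * fx[k] * (1 - fy[k])
    F[i0[k], j0[k] + 1] <- F[i0[k], j0[k] + 1] + vals[k] * (1 - fx[k]) * fy[k]
    F[i0[k] + 1, j0[k] + 1] <- F[i0[k] + 1, j0[k] + 1] + vals[k] * fx[k] * fy[k]
  }
  F
}

# upwind advection + central diffusion for the u and v fields
.ib_predictor <- function(s, dt) {
  nx <- s$nx; ny <- s$ny; dx <- s$dx; dy <- s$dy
  nu <- s$mu / s$rho
  uinf <- s$uinf
  u <- s$u; v <- s$v

  # --- u momentum (interior faces i = 2..nx, all j) ---
  # ghost rows for y boundaries (Dirichlet freestream walls)
  ug <- rbind(u[1, ], u, u[nx + 1, ])              # x-ghosts: clamp (i=1 inflow, i=nx+1 copy)
  ug <- cbind(2 * uinf[1] - ug[, 1], ug, 2 * uinf[1] - ug[, ny])
  # ug index (i+1, j+1) corresponds to u[i, j]
  I <- 2:(nx + 2); J <- 2:(ny + 1)
  uc <- ug[I, J]
  uxm <- (uc - ug[I - 1, J]) / dx
  uxp <- (ug[I + 1, J] - uc) / dx
  uym <- (uc - ug[I, J - 1]) / dy
  uyp <- (ug[I, J + 1] - uc) / dy
  # v averaged to u nodes; clamp at x ends
  vpadx <- rbind(v[1, ], v, v[nx, ])
  vat_u <- 0.25 * (vpadx[1:(nx + 1), 1:ny] + vpadx[2:(nx + 2), 1:ny] +
                   vpadx[1:(nx + 1), 2:(ny + 1)] + vpadx[2:(nx + 2), 2:(ny + 1)])
  adv_u <- pmax(uc, 0) * uxm + pmin(uc, 0) * uxp +
           pmax(vat_u, 0) * uym + pmin(vat_u, 0) * uyp
  lap_u <- (ug[I + 1, J] - 2 * uc + ug[I - 1, J]) / dx^2 +
           (ug[I, J + 1] - 2 * uc + ug[I, J - 1]) / dy^2
  ustar <- u + dt * (-adv_u + nu * lap_u)
  ustar[1, ] <- uinf[1]                 # inflow
  ustar[nx + 1, ] <- ustar[nx, ]        # outflow, zero gradient

  # --- v momentum (faces j = 2..ny interior; j = 1, ny+1 Dirichlet) ---
  vgx <- rbind(2 * uinf[2] - v[1, ], v, v[nx, ])   # left Dirichlet ghost, right copy
  vgy <- cbind(2 * uinf[2] - vgx[, 1], vgx, 2 * uinf[2] - vgx[, ny + 1])
  I2 <- 2:(nx + 1); J2 <- 2:(ny + 2)
  vc <- vgy[I2, J2]
  vxm <- (vc - vgy[I2 - 1, J2]) / dx
  vxp <- (vgy[I2 + 1, J2] - vc) / dx
  vym <- (vc - vgy[I2, J2 - 1]) / dy
  vyp <- (vgy[I2, J2 + 1] - vc) / dy
  upady <- cbind(u[, 1], u, u[, ny])
  uat_v <- 0.25 * (upady[1:nx, 1:(ny + 1)] + upady[2:(nx + 1), 1:(ny + 1)] +
                   upady[1:nx, 2:(ny + 2)] + upady[2:(nx + 1), 2:(ny + 2)])
  adv_v <- pmax(uat_v, 0) * vxm + pmin(uat_v, 0) * vxp +
           pmax(vc, 0) * vym + pmin(vc, 0) * vyp
  lap_v <- (vgy[I2 + 1, J2] - 2 * vc + vgy[I2 - 1, J2]) / dx^2 +
           (vgy[I2, J2 + 1] - 2 * vc + vgy[I2, J2 - 1]) / dy^2
  vstar <- v + dt * (-adv_v + nu * lap_v)
  vstar[, 1] <- uinf[2]; vstar[, ny + 1] <- uinf[2]

  list(u = ustar, v = vstar)
}

#' Advance the immersed-boundary solver one step
#'
#' Explicit upwind/central predictor, multidirect immersed-boundary forcing
#' at the markers, then a pressure projection enforcing the discrete
#' divergence constraint.
#'
#' @param s an [ib_flow_state][ib_flow_init()].
#' @param dt time step, s (caller is responsible for CFL; see
#'   [ib_stable_dt()]).
#' @param markers optional immersed boundary: list with vectors `x`, `y`
#'   (positions, m), `u`, `v` (desired velocities, m/s) and `ds` (arc length
#'   per marker, m).
#' @param n_forcing multidirect forcing sweeps.
#' @return updated state; when markers are present, attribute `marker_force`
#'   holds the per-marker fluid force per unit span (N/m, columns `fx`, `fy`)
#'   exerted on the body, and `body_force` the integrated force.
#' @export
ib_flow_step <- function(s, dt, markers = NULL, n_forcing = 3) {
  stopifnot(dt > 0)
  nx <- s$nx; ny <- s$ny; dx <- s$dx; dy <- s$dy
  pred <- .ib_predictor(s, dt)
  u <- pred$u; v <- pred$v

  mf <- NULL
  if (!is.null(markers) && length(markers$x) > 0) {
    du_acc <- numeric(length(markers$x))
    dv_acc <- numeric(length(markers$x))
    # staggered-node origins
    ox_u <- s$x0; oy_u <- s$y0 + dy / 2
    ox_v <- s$x0 + dx / 2; oy_v <- s$y0
    for (it in seq_len(n_forcing)) {
      uk <- .ib_interp(u, ox_u, oy_u, dx, dy, markers$x, markers$y)
      vk <- .ib_interp(v, ox_v, oy_v, dx, dy, markers$x, markers$y)
      du <- markers$u - uk
      dv <- markers$v - vk
      u <- .ib_spread(u, ox_u, oy_u, dx, dy, markers$x, markers$y, du)
      v <- .ib_spread(v, ox_v, oy_v, dx, dy, markers$x, markers$y, dv)
      du_acc <- du_acc + du
      dv_acc <- dv_acc + dv
    }
    # momentum imparted to the fluid; reaction acts on the body
    fx <- -s$rho * du_acc * dx * dy / dt
    fy <- -s$rho * dv_acc * dx * dy / dt
    mf <- cbind(fx = fx, fy = fy)
  }

  # projection
  div <- (u[2:(nx + 1), ] - u[1:nx, ]) / dx + (v[, 2:(ny + 1)] - v[, 1:ny]) / dy
  # the assembled operator is the negative Laplacian (SPD)
  rhs <- -as.vector(div) * s$rho / dt
  p <- matrix(as.numeric(Matrix::solve(s$poisson, rhs)), nx, ny)
  u[2:nx, ] <- u[2:nx, ] - dt / s$rho * (p[2:nx, ] - p[1:(nx - 1), ]) / dx
  # outflow face sees the Dirichlet p = 0 ghost
  u[nx + 1, ] <- u[nx + 1, ] - dt / s$rho * (0 - p[nx, ]) * 2 / dx
  v[, 2:ny] <- v[, 2:ny] - dt / s$rho * (p[, 2:ny] - p[, 1:(ny - 1)]) / dy

  s$u <- u; s$v <- v; s$p <- p; s$t <- s$t + dt
  if (!is.null(mf)) {
    attr(s, "marker_force") <- mf
    attr(s, "body_force") <- colSums(mf)
  }
  s
}

#' Largest stable explicit time step for the current state
#'
#' @param s an [ib_flow_state][ib_flow_init()].
#' @param cfl Courant number.
#' @return time step, s, combining convective and diffusive limits.
#' @export
ib_stable_dt <- function(s, cfl = 0.4) {
  umax <- max(abs(s$u), abs(s$v), 1e-12)
  nu <- s$mu / s$rho
  min(cfl * min(s$dx, s$dy) / umax,
      0.2 * min(s$dx, s$dy)^2 / nu)
}

#' Maximum absolute discrete divergence of the velocity field
#'
#' @param s an [ib_flow_state][ib_flow_init()].
#' @return max-norm of the cell divergences, 1/s.
#' @export
ib_divergence <- function(s) {
  nx <- s$nx; ny <- s$ny
  div <- (s$u[2:(nx + 1), ] - s$u[1:nx, ]) / s$dx +
    (s$v[, 2:(ny + 1)] - s$v[, 1:ny]) / s$dy
  max(abs(div))
}

#' Immersed-boundary load provider for the coupled solver
#'
#' Presents the Navier-Stokes solver through the same provider interface as
#' [oracle_provider()]: each `eval` re-advances the flow from the committed
#' state under the candidate plate kinematics (sub-stepping to respect the
#' explicit stability limit) and returns chordwise load distributions;
#' `commit` accepts the last advance once the coupling iteration has
#' converged.
#'
#' @param mesh a [beam_mesh()] (chord stations become the markers).
#' @param flight a [flight_condition()].
#' @param kin a [kinematic_spec()] (stroke plane orientation and amplitude
#'   set the domain and freestream).
#' @param nx,ny grid cells.
#' @param domain_chords domain extents as multiples of the chord:
#'   `c(upstream, downstream, half_height)`.
#' @param cfl Courant number for sub-stepping.
#' @return provider list with `eval`, `commit` and the underlying `state`
#'   accessor `get_state`.
#' @export
ib_flow_provider <- function(mesh, flight, kin, nx = 96, ny = 96,
                             domain_chords = c(3, 6, 3), cfl = 0.4) {
  c_chord <- mesh$length
  uinf <- freestream_solver_frame(flight$V, kin$beta)
  Lx <- (domain_chords[1] + 1 + domain_chords[2]) * c_chord
  half <- max(domain_chords[3] * c_chord, 1.5 * kin$zeta_a + c_chord)
  x0 <- -domain_chords[1] * c_chord
  env <- new.env(parent = emptyenv())
  env$committed <- ib_flow_init(nx, ny, Lx, 2 * half, x0 = x0, y0 = -half,
                                rho = flight$rho_air, mu = flight$mu, uinf = uinf)
  env$pending <- NULL
  xs <- mesh$node_x
  ds <- c(diff(xs) / 2, 0) + c(0, diff(xs) / 2)

  list(
    eval = function(kin_nodes, t, dt) {
      st <- env$committed
      n_sub <- max(1L, ceiling(dt / ib_stable_dt(st, cfl)))
      dts <- dt / n_sub
      markers <- list(x = xs, y = kin_nodes$w, u = rep(0, length(xs)),
                      v = kin_nodes$w_dot, ds = ds)
      fx_acc <- numeric(length(xs)); fy_acc <- numeric(length(xs))
      for (ss in seq_len(n_sub)) {
        st <- ib_flow_step(st, dts, markers = markers)
        mf <- attr(st, "marker_force")
        fx_acc <- fx_acc + mf[, "fx"]
        fy_acc <- fy_acc + mf[, "fy"]
      }
      fx <- fx_acc / n_sub / ds   # per unit chord length, per unit span
      fy <- fy_acc / n_sub / ds
      env$pending <- st
      list(fx = fx, fy = fy, q = fy, Fx = sum(fx * ds), Fy = sum(fy * ds))
    },
    commit = function() {
      if (!is.null(env$pending)) env$committed <- env$pending
      invisible(NULL)
    },
    get_state = function() env$committed,
    mode = "cfd"
  )
}
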