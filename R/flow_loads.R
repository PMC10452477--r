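#' Integrate pressure and shear loads over a surface
#'
#' Surface traction `t = -p n + mu (grad u + grad u^T) n` integrated over the
#' stations of a discretised surface, per unit span.
#'
#' @param surface data.frame with station positions `x`, `y`, outward unit
#'   normals `nx`, `ny` and panel lengths `ds` (m).
#' @param p_fun function `(x, y) -> pressure` (Pa), vectorised.
#' @param gradu_fun optional function `(x, y) -> list(ux, uy, vx, vy)` of
#'   velocity gradients (1/s), vectorised; omitted = pressure only.
#' @param mu dynamic viscosity, Pa s.
#' @return object of class `load_distribution`: per-station traction
#'   components `fx`, `fy` (N/m^2) and net force `Fx`, `Fy` (N/m per unit
#'   span).
#' @export
compute_loads <- function(surface, p_fun, gradu_fun = NULL, mu = 0) {
  need <- c("x", "y", "nx", "ny", "ds")
  if (!all(need %in% names(surface))) {
    stop("surface needs columns ", paste(need, collapse = ", "))
  }
  if (any(surface$ds <= 0)) stop("degenerate surface panel (ds <= 0)")
  nrm <- sqrt(surface$nx^2 + surface$ny^2)
  if (any(abs(nrm - 1) > 1e-8)) stop("surface normals must be unit vectors")
  p <- p_fun(surface$x, surface$y)
  fx <- -p * surface$nx
  fy <- -p * surface$ny
  if (!is.null(gradu_fun) && mu > 0) {
    g <- gradu_fun(surface$x, surface$y)
    # tau = mu (grad u + grad u^T)
    fx <- fx + mu * (2 * g$ux * surface$nx + (g$uy + g$vx) * surface$ny)
    fy <- fy + mu * ((g$uy + g$vx) * surface$nx + 2 * g$vy * surface$ny)
  }
  structure(
    list(stations = data.frame(x = surface$x, y = surface$y, fx = fx, fy = fy,
                               ds = surface$ds),
         Fx = sum(fx * surface$ds), Fy = sum(fy * surface$ds)),
    class = "load_distribution"
  )
}

#' @export
print.load_distribution <- function(x, ...) {
  cat(sprintf("load_distribution: %d stations, net (Fx, Fy) = (%.4g, %.4g) N/m\n",
              nrow(x$stations), x$Fx, x$Fy))
  invisible(x)
}

#' Write a flow snapshot as legacy ASCII VTK
#'
#' Exports cell-centred velocity and pressure (and the normalised gauge
#' pressure `(p - p_inf) / (rho V^2)` when a reference speed is supplied) of
#' an immersed-boundary state as a VTK structured-points file readable by
#' ParaView.
#'
#' @param s an [ib_flow_state][ib_flow_init()].
#' @param path output `.vtk` file.
#' @param v_ref reference speed for pressure normalisation, m/s (optional).
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(s, path, v_ref = NULL) {
  nx <- s$nx; ny <- s$ny
  uc <- (s$u[1:nx, ] + s$u[2:(nx + 1), ]) / 2
  vc <- (s$v[, 1:ny] + s$v[, 2:(ny + 1)]) / 2
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("flow snapshot t=%.6g", s$t),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx, ny),
               sprintf("ORIGIN %g %g 0", s$x0 + s$dx / 2, s$y0 + s$dy / 2),
               sprintf("SPACING %g %g 1", s$dx, s$dy),
               sprintf("POINT_DATA %d", nx * ny),
               "VECTORS velocity double"), con)
  writeLines(sprintf("%.8g %.8g 0", as.vector(uc), as.vector(vc)), con)
  writeLines(c("SCALARS pressure double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%.8g", as.vector(s$p)), con)
  if (!is.null(v_ref) && v_ref > 0) {
    writeLines(c("SCALARS pressure_normalized double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.8g", as.vector(s$p) / (s$rho * v_ref^2)), con)
  }
  invisible(path)
}
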