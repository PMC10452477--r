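#' Radial basis function mesh deformation
#'
#' Propagates prescribed boundary displacements into a cloud of mesh nodes by
#' RBF interpolation with the compactly supported Wendland C2 kernel plus a
#' full linear polynomial, so constant and linear displacement fields
#' (rigid translations, uniform stretches) are reproduced exactly and the
#' interpolant matches the control points exactly.
#'
#' @param nodes `n x 2` matrix of node coordinates to displace.
#' @param control `m x 2` matrix of control-point coordinates (wing surface
#'   plus any fixed outer-boundary points).
#' @param displacement `m x 2` matrix of control-point displacements (zero
#'   rows pin the outer boundary).
#' @param support kernel support radius (default 10x the control-cloud
#'   diameter scale).
#' @return `n x 2` matrix of displaced node coordinates.
#' @export
rbf_deform <- function(nodes, control, displacement, support = NULL) {
  nodes <- as.matrix(nodes); control <- as.matrix(control)
  displacement <- as.matrix(displacement)
  stopifnot(ncol(nodes) == 2, ncol(control) == 2,
            nrow(displacement) == nrow(control), ncol(displacement) == 2)
  m <- nrow(control)
  if (is.null(support)) {
    support <- 10 * max(diff(range(control[, 1])), diff(range(control[, 2])), 1e-12)
  }
  wendland <- function(r) {
    q <- pmin(r / support, 1)
    (1 - q)^4 * (4 * q + 1)
  }
  D <- as.matrix(stats::dist(control))
  Phi <- wendland(D)
  P <- cbind(1, control)
  A <- rbind(cbind(Phi, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, rbind(displacement, matrix(0, 3, 2)))
  dx <- outer(nodes[, 1], control[, 1], "-")
  dy <- outer(nodes[, 2], control[, 2], "-")
  Phi_eval <- wendland(sqrt(dx^2 + dy^2))
  disp <- Phi_eval %*% coef[1:m, ] + cbind(1, nodes) %*% coef[(m + 1):(m + 3), ]
  nodes + disp
}

#' Deform a body-fitted mesh to follow the wing surface
#'
#' Thin wrapper over [rbf_deform()]: wing-surface nodes are control points
#' carrying the prescribed displacements, outer-boundary nodes are zero-
#' displacement control points, and interior nodes follow the interpolant.
#' Errors if any cell of a supplied quad connectivity inverts.
#'
#' @param mesh list with `nodes` (`n x 2`), index vectors `surface` and
#'   `outer`, and optionally `quads` (`k x 4` node indices).
#' @param surface_displacement displacement of the surface nodes
#'   (`length(surface) x 2`).
#' @param support RBF support radius.
#' @return the mesh with displaced `nodes`.
#' @export
deform_mesh <- function(mesh, surface_displacement, support = NULL) {
  stopifnot(!is.null(mesh$nodes), !is.null(mesh$surface), !is.null(mesh$outer))
  sd <- as.matrix(surface_displacement)
  control <- rbind(mesh$nodes[mesh$surface, , drop = FALSE],
                   mesh$nodes[mesh$outer, , drop = FALSE])
  disp <- rbind(sd, matrix(0, length(mesh$outer), 2))
  mesh$nodes <- rbf_deform(mesh$nodes, control, disp, support)
  if (!is.null(mesh$quads)) {
    a <- .quad_areas(mesh$nodes, mesh$quads)
    if (any(a <= 0)) stop("mesh deformation inverted ", sum(a <= 0), " cell(s)")
  }
  mesh
}

# signed areas (counterclockwise node ordering assumed); <= 0 marks inversion
.quad_areas <- function(nodes, quads) {
  x <- matrix(nodes[quads, 1], nrow(quads), 4)
  y <- matrix(nodes[quads, 2], nrow(quads), 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
         (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
         (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}
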