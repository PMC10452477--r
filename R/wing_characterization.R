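#' Linear stiffness fit of force-deflection records
#'
#' Ordinary least squares of mean force on deflection for one bending
#' direction, the reduction applied to bench force-deflection measurements.
#'
#' @param records data.frame with columns `direction`, `l_m`, `delta_m`,
#'   `force_N` and `n` (see [gen_force_deflection()] for the schema).
#' @param direction optional filter, `"spanwise"` or `"chordwise"`; required
#'   when `records` mixes directions.
#' @return object of class `stiffness_fit` with `slope` (N/m), `intercept`
#'   (N) and `r_squared`.
#' @export
fit_force_deflection <- function(records, direction = NULL) {
  records <- .validate_fd_records(records)
  if (!is.null(direction)) records <- records[records$direction == direction, , drop = FALSE]
  if (length(unique(records$direction)) > 1) {
    stop("records mix directions; pass `direction` to select one")
  }
  if (length(unique(records$delta_m)) < 2) {
    stop("need at least 2 distinct deflections for a stiffness fit")
  }
  fit <- stats::lm(force_N ~ delta_m, data = records)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((records$force_N - mean(records$force_N))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, n = nrow(records),
         direction = unique(records$direction)),
    class = "stiffness_fit"
  )
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat(sprintf("stiffness_fit (%s): slope = %.4g N/m, intercept = %.3g N, r^2 = %.3f (n = %d)\n",
              x$direction, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

.validate_fd_records <- function(records) {
  need <- c("direction", "l_m", "delta_m", "force_N")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("force-deflection records missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(records$delta_m)) || any(!is.finite(records$force_N))) {
    stop("non-finite values in force-deflection records")
  }
  records
}

#' Effective strip width for a bending direction
#'
#' The measurement model treats each bending test as a uniform cantilever
#' strip. Spanwise bending engages the full chord as strip width; the
#' chordwise point load deflects only a local band of the wing, represented
#' by a quarter-chord effective width. These widths, with the measured
#' moduli, reproduce the magnitude and ~6x spanwise/chordwise ratio of the
#' bench force measurements.
#'
#' @param wing a [wing_spec()].
#' @param direction `"spanwise"` or `"chordwise"`.
#' @return strip width in m.
#' @export
strip_width <- function(wing, direction) {
  switch(match.arg(direction, c("spanwise", "chordwise")),
         spanwise = wing$c,
         chordwise = wing$c / 4)
}

# cantilever strip length and default load station for a direction
.strip_geometry <- function(wing, direction) {
  switch(match.arg(direction, c("spanwise", "chordwise")),
         spanwise = list(length = wing$R, l = 0.7 * wing$R),
         chordwise = list(length = wing$c, l = 0.7 * wing$c))
}

#' Calibrate an effective elastic modulus by inverse finite-element matching
#'
#' Finds the homogeneous modulus `E` for which the static cantilever-strip
#' finite-element model reproduces the measured force/deflection slope: the
#' point load is applied at the records' active length and the deflection
#' read at the load point, and `E` is solved by bracketed root finding to a
#' relative tolerance of 1e-6.
#'
#' @param records force-deflection records of one direction.
#' @param wing a [wing_spec()] providing thickness and planform.
#' @param direction `"spanwise"` or `"chordwise"`.
#' @param width strip width override, m (see [strip_width()]).
#' @param n_elements finite elements in the strip model.
#' @param bracket modulus search interval, Pa.
#' @return calibrated modulus, Pa.
#' @export
calibrate_modulus <- function(records, wing, direction,
                              width = strip_width(wing, direction),
                              n_elements = 50, bracket = c(1e5, 1e13)) {
  fit <- fit_force_deflection(records, direction)
  if (!is.finite(fit$slope) || fit$slope <= 0) {
    stop(sprintf("measured stiffness slope %.3g N/m is not positive; cannot calibrate", fit$slope))
  }
  geom <- .strip_geometry(wing, direction)
  l <- stats::median(records$l_m[records$direction == direction])
  if (!is.finite(l) || l <= 0) l <- geom$l
  I_strip <- width * wing$hw^3 / 12

  # slope (N/m) the strip FEM predicts at modulus E; load and readout at x = l.
  # The strip width enters through I_strip, so forces here are whole-strip N.
  model_slope <- function(E) {
    mesh <- beam_mesh(n_elements, geom$length, E * I_strip, wing$rho_w * wing$hw)
    sol <- static_solve(mesh, 1, l)  # unit load per unit span
    delta <- sol$w_at(l)
    1 / delta
  }
  g <- function(E) model_slope(E) - fit$slope
  lo <- g(bracket[1]); hi <- g(bracket[2])
  if (sign(lo) == sign(hi)) {
    stop(sprintf(paste0("modulus root not bracketed: model slope spans [%.3g, %.3g] N/m ",
                        "over E in [%.3g, %.3g] Pa but measured slope is %.3g N/m"),
                 model_slope(bracket[1]), model_slope(bracket[2]),
                 bracket[1], bracket[2], fit$slope))
  }
  stats::uniroot(g, interval = bracket, tol = 1e-12, extendInt = "no",
                 f.lower = lo, f.upper = hi)$root
}

#' First in-vacuo chordwise natural frequency of the plate strip
#'
#' Closed-form first cantilever mode of a uniform strip,
#' `f1 = (lambda^2 / 2 pi) sqrt(E hw^2 / (12 rho_w c^4))` with
#' `lambda = 1.875104`. Being an in-vacuo structural quantity it carries no
#' added-mass correction: the frequency ratio depends only on the wing's
#' structural properties, not the fluid density.
#'
#' @param wing a [wing_spec()].
#' @return frequency in Hz.
#' @export
natural_frequency_chordwise <- function(wing) {
  stopifnot(wing$E_chord > 0, wing$rho_w > 0, wing$hw > 0, wing$c > 0)
  lambda1 <- 1.875104
  (lambda1^2 / (2 * pi)) * sqrt(wing$E_chord * wing$hw^2 / (12 * wing$rho_w * wing$c^4))
}

#' Flapping-to-natural frequency ratio
#'
#' @param f flapping frequency, Hz.
#' @param f1 first chordwise natural frequency, Hz.
#' @return dimensionless ratio `f / f1`.
#' @export
frequency_ratio <- function(f, f1) {
  if (!is.finite(f1) || f1 <= 0) stop("natural frequency must be positive")
  f / f1
}

#' Serialise a calibrated wing specification to JSON
#'
#' @param wing a [wing_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_wing_spec <- function(wing, path) {
  jsonlite::write_json(unclass(wing), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a wing specification from JSON
#'
#' @param path JSON file written by [write_wing_spec()].
#' @return a [wing_spec()].
#' @export
read_wing_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  wing_spec(R = x$R, c = x$c, hw = x$hw, mw = x$mw, Vw = x$Vw,
            rho_w = x$rho_w, E_chord = x$E_chord, E_span = x$E_span, S = x$S)
}
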