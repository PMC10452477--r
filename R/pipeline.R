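#' Build a run configuration
#'
#' Defaults describe the reference study conditions: the measured monarch
#' wing, 31 mm plunge amplitude at 10 Hz, and the altitude band from near sea
#' level to the overwintering range. All fields are plain values so a run is
#' fully reproducible from its serialised manifest.
#'
#' @param ... overrides of the default fields (partial lists are merged
#'   recursively).
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  base <- list(
    wing = list(R = 0.05, c = 2.9e-2, hw = 1.6e-4, mw = 1.5e-5, Vw = 4.82e-8,
                E_chord = 0.3e9, E_span = 2.5e9),
    kinematics = list(zeta_a = 31e-3, f = 10, beta_deg = 0),
    flight = list(altitude = 3000, V = 0.6, mu = isa_constants$mu),
    design = list(rho_air = c(0.91, 1.2), beta_deg = c(0, 60), V = c(0.5, 1.5),
                  n_per_axis = 5, mode = "grid",
                  altitude_grid = seq(193, 3000, length.out = 8),
                  L_target = 5e-3, L_tol = 1e-4, re_tol = 0.10, re_degree = 2),
    solver = list(mode = "oracle", n_elements = 12, steps_per_cycle = 160,
                  n_cycles = 3, cfd_nx = 64, cfd_ny = 64),
    seed = 1,
    out_dir = "flapfsi-out"
  )
  over <- list(...)
  merge2 <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) merge2(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  structure(merge2(base, over), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys mirror [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.config_wing <- function(cfg) {
  do.call(wing_spec, cfg$wing)
}

.config_kin <- function(cfg) {
  kinematic_spec(zeta_a = cfg$kinematics$zeta_a, f = cfg$kinematics$f,
                 beta = cfg$kinematics$beta_deg * pi / 180)
}

.write_manifest <- function(cfg, path, extra = list()) {
  jsonlite::write_json(c(list(config = unclass(cfg),
                              package_version = as.character(utils::packageVersion("flapfsi")),
                              r_version = R.version.string),
                         extra),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Characterisation stage: reduce force-deflection data to a calibrated wing
#'
#' Reads force-deflection records from CSV (columns `direction`, `l_m`,
#' `delta_m`, `force_N`, `n`) or generates synthetic bench data, fits both
#' directions, calibrates the chordwise and spanwise moduli by inverse FEM,
#' and writes the calibrated wing specification, fit report and manifest.
#'
#' @param config a [run_config()].
#' @param records_csv CSV path, or `NULL` to generate synthetic records with
#'   `config$seed`.
#' @return list with the calibrated `wing`, both `fits` and output paths.
#' @export
run_characterize <- function(config = run_config(), records_csv = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wing0 <- .config_wing(config)
  records <- if (is.null(records_csv)) {
    noise <- measurement_noise_model(seed = config$seed)
    rbind(gen_force_deflection("chordwise", noise = noise, wing = wing0),
          gen_force_deflection("spanwise", noise = noise, wing = wing0))
  } else {
    if (!file.exists(records_csv)) stop("records file not found: ", records_csv)
    r <- utils::read.csv(records_csv)
    .validate_fd_records(r)
  }
  fits <- list()
  wing <- wing0
  for (dir in intersect(c("chordwise", "spanwise"), unique(records$direction))) {
    sub <- records[records$direction == dir, , drop = FALSE]
    if (nrow(sub) < 3) warning("only ", nrow(sub), " ", dir, " records; fit is fragile")
    fits[[dir]] <- fit_force_deflection(sub)
    E <- calibrate_modulus(sub, wing0, dir)
    if (dir == "chordwise") wing$E_chord <- E else wing$E_span <- E
  }
  f1 <- natural_frequency_chordwise(wing)
  spec_path <- file.path(config$out_dir, "wing_spec.json")
  write_wing_spec(wing, spec_path)
  report <- list(
    fits = lapply(fits, unclass),
    rho_w = wing$rho_w, f1_chordwise = f1,
    frequency_ratio = frequency_ratio(config$kinematics$f, f1))
  report_path <- file.path(config$out_dir, "characterization.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(config, file.path(config$out_dir, "manifest_characterize.json"))
  list(wing = wing, fits = fits, spec_path = spec_path, report_path = report_path)
}

#' Simulation stage: one coupled run at the configured flight condition
#'
#' @param config a [run_config()].
#' @param wing optional calibrated [wing_spec()] (defaults to the config wing).
#' @return list with the `solution`, its `performance` and output paths.
#' @export
run_simulate <- function(config = run_config(), wing = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(wing)) wing <- .config_wing(config)
  kin <- .config_kin(config)
  if (kin$beta >= pi / 2) stop("stroke plane angle must be below 90 deg")
  fl <- flight_condition(altitude = config$flight$altitude, V = config$flight$V,
                         mu = config$flight$mu, c = wing$c)
  sv <- config$solver
  sol <- run_cycles(wing, kin, fl, n_cycles = sv$n_cycles, mode = sv$mode,
                    n_elements = sv$n_elements, steps_per_cycle = sv$steps_per_cycle,
                    cfd = if (sv$mode == "cfd") list(nx = sv$cfd_nx, ny = sv$cfd_ny) else list())
  perf <- cycle_performance(sol, fl, cycle_index = sv$n_cycles)
  series_path <- file.path(config$out_dir, "timeseries.csv")
  write_solution_csv(sol, series_path)
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(list(performance = unclass(perf),
                            periodicity = sol$periodicity,
                            mean_inner_iterations = sol$mean_inner),
                       summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .write_manifest(config, file.path(config$out_dir, "manifest_simulate.json"),
                  extra = list(periodicity = sol$periodicity))
  list(solution = sol, performance = perf,
       series_path = series_path, summary_path = summary_path)
}

#' Altitude-sweep stage: surrogate-assisted equilibrium branch
#'
#' Evaluates the design space with the coupled solver, trains the MLP
#' surrogate, fits the Reynolds-vs-altitude polynomial to (synthetic or
#' supplied) flight observations, selects the equilibrium branch on the
#' configured altitude grid, and writes branch CSV, surrogate JSON and a
#' manifest.
#'
#' @param config a [run_config()].
#' @param wing optional calibrated [wing_spec()].
#' @param observations optional data.frame with columns `h`, `Re` (defaults
#'   to [gen_flight_observations()] on the altitude grid, seeded).
#' @return list with `points`, `surrogate`, `re_fit`, `branch` and paths.
#' @export
run_altitude_sweep <- function(config = run_config(), wing = NULL,
                               observations = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(wing)) wing <- .config_wing(config)
  ds <- config$design
  ranges <- list(rho_air = ds$rho_air, beta = ds$beta_deg * pi / 180, V = ds$V)
  points <- sample_design_space(ranges, ds$n_per_axis, ds$mode, seed = config$seed)
  points <- evaluate_design_points(points, wing = wing,
                                   zeta_a = config$kinematics$zeta_a,
                                   f = config$kinematics$f,
                                   mode = config$solver$mode,
                                   n_elements = config$solver$n_elements,
                                   steps_per_cycle = config$solver$steps_per_cycle,
                                   n_cycles = config$solver$n_cycles,
                                   mu = config$flight$mu)
  surrogate <- train_surrogate(points, seed = config$seed)
  if (is.null(observations)) {
    observations <- gen_flight_observations(
      seq(min(ds$altitude_grid), max(ds$altitude_grid), length.out = 12),
      seed = config$seed, c = wing$c, mu = config$flight$mu)
  }
  re_fit <- fit_re_polynomial(observations, degree = ds$re_degree)
  crit <- equilibrium_criteria(L_target = ds$L_target, L_tol = ds$L_tol,
                               re_fit = re_fit, re_tol = ds$re_tol)
  branch <- select_equilibrium(surrogate, crit, ds$altitude_grid,
                               beta_range = ranges$beta, V_range = ranges$V,
                               c_ref = wing$c, mu = config$flight$mu)
  branch_path <- file.path(config$out_dir, "equilibrium_branch.csv")
  utils::write.csv(branch, branch_path, row.names = FALSE)
  points_path <- file.path(config$out_dir, "design_points.csv")
  utils::write.csv(points, points_path, row.names = FALSE)
  surrogate_path <- file.path(config$out_dir, "surrogate.json")
  write_surrogate(surrogate, surrogate_path)
  .write_manifest(config, file.path(config$out_dir, "manifest_sweep.json"),
                  extra = list(n_design_points = nrow(points),
                               train_rmse = as.list(surrogate$train_rmse),
                               re_coefficients = re_fit$coefficients))
  list(points = points, surrogate = surrogate, re_fit = re_fit, branch = branch,
       branch_path = branch_path, points_path = points_path,
       surrogate_path = surrogate_path)
}
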