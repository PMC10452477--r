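# Shared fixtures for the suite.

ref_wing <- function(...) wing_spec(...)

# cheap coupled oracle run used by several tests
quick_run <- function(beta = 30 * pi / 180, V = 1.0, rho_air = NULL,
                      altitude = if (is.null(rho_air)) 3000 else NULL,
                      wing = ref_wing(), n_cycles = 3, n_elements = 10,
                      steps_per_cycle = 120, ...) {
  kin <- kinematic_spec(beta = beta)
  fl <- flight_condition(altitude = altitude, rho_air = rho_air, V = V, c = wing$c)
  run_cycles(wing, kin, fl, n_cycles = n_cycles, mode = "oracle",
             n_elements = n_elements, steps_per_cycle = steps_per_cycle, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# analytic clamped-free cantilever frequencies, Hz
analytic_cantilever_freqs <- function(EI, mu_m, L, n = 3) {
  lam <- c(1.875104, 4.694091, 7.854757)[seq_len(n)]
  lam^2 / (2 * pi * L^2) * sqrt(EI / mu_m)
}
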