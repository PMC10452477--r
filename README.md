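# flapfsi

Aeroelastic analysis of chordwise-flexible flapping wings across altitude.

`flapfsi` models an insect-scale wing whose chord section bends passively
while the leading edge is plunged sinusoidally along an inclined stroke
plane, and studies how the equilibrium flight condition and its power
budget change as air density falls with altitude. Lower density reduces the
aerodynamic part of the actuation power while the inertial part stays
essentially constant, so level flight gets cheaper at altitude provided the
wing can still generate the required lift — which it does by flying slower,
at a steeper stroke plane and a higher lift coefficient.

## What is in the package

* **Atmosphere** — ISA troposphere density/altitude conversions
  (`density_at_altitude()`, `altitude_at_density()`).
* **Wing characterization** — reduction of bench force–deflection records
  to bending stiffnesses (`fit_force_deflection()`) and effective moduli by
  inverse finite-element calibration (`calibrate_modulus()`); chordwise
  natural frequency and flapping-to-natural frequency ratio
  (`natural_frequency_chordwise()`, `frequency_ratio()`).
* **Structure** — Hermite-cubic Euler–Bernoulli beam FEM with a moving
  clamped leading edge and Newmark time integration (`beam_mesh()`,
  `step_dynamic()`); passive pitch and first-harmonic summaries.
* **Flow** — 2-D incompressible Navier–Stokes on a staggered grid with an
  immersed moving plate (`ib_flow_init()`, `ib_flow_step()`), a spectral
  verification solver, surface load integration, and RBF mesh deformation.
* **Coupling** — partitioned FSI with Aitken dynamic relaxation
  (`coupled_step()`, `run_cycles()`), with a fast quasi-steady aerodynamic
  oracle as the default load model and the Navier–Stokes solver as the
  high-fidelity option.
* **Performance** — cycle-averaged lift/thrust/coefficients, the exact
  aerodynamic + inertial power split, propulsive efficiency, and effective
  angle of attack (`cycle_performance()`).
* **Design space** — sampling, coupled evaluation, a neural-network
  surrogate (`train_surrogate()`), Reynolds-vs-altitude fits, and
  equilibrium flight selection across altitude (`select_equilibrium()`).
* **Synthetic data** — generators for bench records and flight observations
  with calibrated noise models; their defaults are the study conditions.
* **Pipeline** — YAML-configurable `run_characterize()`, `run_simulate()`,
  `run_altitude_sweep()` plus a CLI script at `inst/cli/flapfsi.R`.

See the methods vignette (`vignettes/methods.Rmd`) for the governing
equations, sign conventions, numerical schemes and verification results.

## Worked example

Characterize the reference wing, run three flapping cycles at 3000 m, and
summarize the last cycle:

```r
library(flapfsi)

w  <- wing_spec()                       # 29 mm chord, 0.16 mm membrane
f1 <- natural_frequency_chordwise(w)
c(f1 = f1, ratio = frequency_ratio(10, f1))
#>      f1   ratio
#> 30.1747  0.3314

fl  <- flight_condition(altitude = 3000, V = 1.0, c = w$c)
sol <- run_cycles(w, kinematic_spec(beta = 30 * pi / 180), fl,
                  n_cycles = 3, n_elements = 12, steps_per_cycle = 160)
sol
#> aeroelastic_solution (oracle): 3 cycles x 160 steps, 12 beam elements
#>   periodicity (last-cycle mean-lift drift): 0.00131; mean inner iterations: 6.9

cycle_performance(sol, fl)
# L_bar = 6.04 mN, CL = 4.58, P = 19.9 mW (18.3 aero + 1.5 inertial),
# eta = 0.38, first-harmonic pitch amplitude 0.33 rad
```

Sweep the design space and extract the equilibrium-flight branch versus
altitude (a few minutes with the oracle load model):

```r
pts <- sample_design_space()                      # (rho_air, beta, V) grid
pts <- evaluate_design_points(pts, wing = w)
sur <- train_surrogate(pts, seed = 1)
obs <- gen_flight_observations(seq(193, 3000, length.out = 12), seed = 1)
crit <- equilibrium_criteria(re_fit = fit_re_polynomial(obs))
branch <- select_equilibrium(sur, crit, seq(193, 3000, length.out = 8))
branch[, c("h", "V", "beta", "CL", "P", "Paero", "Pinertial")]
# V decreases and beta, CL increase with altitude; P and Paero fall while
# Pinertial stays nearly constant.
```

The same stages are available from the command line:

```sh
Rscript inst/cli/flapfsi.R characterize --config config.yaml --out out/
Rscript inst/cli/flapfsi.R simulate     --config config.yaml --out out/
Rscript inst/cli/flapfsi.R sweep        --config config.yaml --out out/
```

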