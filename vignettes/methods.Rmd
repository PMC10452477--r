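---
title: "Methods: aeroelastic modelling of a chordwise-flexible flapping wing across altitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aeroelastic modelling of a chordwise-flexible flapping wing across altitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flapfsi)
```

`flapfsi` models the coupled structural and aerodynamic behaviour of an
insect-scale wing whose chordwise cross-section bends passively while the
leading edge is plunged sinusoidally, and asks how the equilibrium flight
condition and its power budget change as air density drops with altitude.
This vignette records the governing equations, sign conventions, numerical
schemes, and tolerances so that every number produced by the package can be
traced to a formula.

## 1. Atmosphere

The troposphere is modelled by the International Standard Atmosphere with a
linear temperature lapse:

$$\rho(h) = \rho_0 \left(1 - \frac{L h}{T_0}\right)^{\frac{g}{R L} - 1},$$

with $\rho_0 = 1.225\ \mathrm{kg\,m^{-3}}$, $T_0 = 288.15\ \mathrm{K}$,
$L = 0.0065\ \mathrm{K\,m^{-1}}$, $g = 9.80665\ \mathrm{m\,s^{-2}}$ and
$R = 287.058\ \mathrm{J\,kg^{-1}K^{-1}}$. `density_at_altitude()` and its
closed-form inverse `altitude_at_density()` implement this; the dynamic
viscosity is held at $\mu = 1.81\times 10^{-5}\ \mathrm{Pa\,s}$, which is
accurate to about 1% over the first 3 km.

```{r}
density_at_altitude(c(193, 3000))
```

## 2. Wing specification and characterization

The wing is a thin rectangular plate: chord $c$, semi-span $R$, thickness
$h_w$, density $\rho_w$. `wing_spec()` accepts either a measured mass (with
planform volume) or $\rho_w$ directly and cross-checks the two when both are
given (they must agree within 5%).

### Stiffness from force–deflection records

Bench records of tip force versus tip deflection are reduced in two steps:

1. `fit_force_deflection()` fits a straight line through the origin to each
   specimen's record, giving a bending stiffness $k = F/\delta$
   (N m$^{-1}$) per specimen and direction.
2. `calibrate_modulus()` finds the effective Young's modulus $E$ such that a
   clamped beam finite-element model of the test strip reproduces the median
   measured stiffness. The inversion is a bracketed root solve on
   $\log E$; because tip stiffness is strictly monotone in $E$ this is
   globally convergent.

The test strips follow the bench geometry: the spanwise strip is one chord
wide, the chordwise strip a quarter chord wide, and the free length is 70%
of the relevant wing dimension. Because chordwise specimens are much floppier
and noisier than spanwise ones, single-specimen chordwise moduli scatter
widely; calibrated values should be interpreted as medians over several
specimens (the synthetic generator and the pipeline both do this).

### Natural frequency and frequency ratio

The first chordwise cantilever frequency of a unit-width strip is

$$f_1 = \frac{\lambda_1^2}{2\pi}\sqrt{\frac{E h_w^2}{12\, \rho_w\, c^4}},
\qquad \lambda_1 = 1.875104,$$

implemented by `natural_frequency_chordwise()`. The flapping-to-natural
frequency ratio `frequency_ratio(f, f1)` is the primary dimensionless
descriptor of chordwise flexibility; values well below one mean the wing is
driven quasi-statically and bends mainly through added-mass and aerodynamic
loading rather than resonance.

```{r}
w <- wing_spec()
f1 <- natural_frequency_chordwise(w)
c(f1 = f1, ratio = frequency_ratio(10, f1))
```

## 3. Kinematics and the stroke-plane convention

The leading edge is plunged along the stroke plane,
$\zeta(t) = \zeta_a \cos(2\pi f t)$, with amplitude related to the angular
stroke amplitude by $\zeta_a = R\, r_2 \sin\psi_a$ (`amplitude_from_angular()`).

All two-dimensional solvers work in a frame attached to the stroke plane:
$x$ along the chord at rest, $y$ along the plunge direction. The stroke
plane is inclined by $\beta$ to the oncoming flow of speed $V$, so the
freestream seen by the section is

$$\mathbf{u}_\infty = (V\cos\beta,\ V\sin\beta),$$

i.e. the mean incidence of the chord equals $+\beta$
(`freestream_solver_frame()`). Solver-frame forces $(F_x, F_y)$ are resolved
back to the flight frame by

$$L = -F_x \sin\beta + F_y \cos\beta, \qquad
T = -F_x \cos\beta - F_y \sin\beta,$$

(`resolve_forces()`), which reduces to $L = F_y$, $T = -F_x$ at $\beta = 0$
and preserves the force magnitude. The instantaneous effective angle of
attack combines the passive pitch $\alpha$, the plunge-induced inflow and
the stroke-plane inclination:

$$\alpha_\mathrm{eff}(t) = \alpha(t) - \arctan\!\frac{\dot\zeta(t)}{V} + \beta.$$

## 4. Structural model

The chord section is an Euler–Bernoulli beam discretized with two-node
Hermite-cubic elements (transverse displacement $w$ and rotation $\theta$
per node; `beam_mesh()`). The leading edge is a clamped, moving support:
$w_1 = \zeta(t)$, $\theta_1 = 0$. Time integration uses the Newmark
average-acceleration scheme ($\beta = 1/4$, $\gamma = 1/2$), which is
unconditionally stable and conserves energy for linear free vibration; the
effective stiffness matrix is Cholesky-factorized once per time-step size
(`newmark_operator()`, `step_dynamic()`).

The passive pitch angle reported in time series is the geometric angle of
the chord line from leading to trailing edge,
$\alpha = \arctan[(w_\mathrm{TE} - \zeta)/c]$ relative to the stroke plane
(`passive_pitch()`), summarized over a cycle by a first-harmonic least-squares
fit `first_harmonic_fit()` returning amplitude and phase relative to the
plunge.

Verification: tip- and mid-span static loads match the cantilever closed
forms to 0.1%; the first three natural frequencies converge at second order
to the analytic values; free vibration conserves energy to 0.1% over 100
periods.

## 5. Aerodynamic load models

### Quasi-steady oracle

The default load provider (`oracle_provider()`, configured by
`oracle_config()`) is a strip-wise quasi-steady model with two parts, per
unit chordwise length:

* a non-circulatory added-mass reaction $-\tfrac{\pi}{4}\rho\, c\, a_n$,
  where $a_n$ is the plate-normal acceleration, and
* a circulatory normal force $\tfrac12 \rho |\mathbf{u}_{rel}|^2 C_n$ with
  $C_n = 2\pi \sin\alpha_{loc} |\cos\alpha_{loc}|$, the flat-plate law whose
  $\sin\cos$ form self-limits beyond stall.

The relative velocity includes the freestream and the local plate velocity.
The oracle is deliberately simple — it is a fast stand-in for the full
viscous flow that preserves the couplings that matter here (added-mass
feedback on the structure, density scaling of aerodynamic power, and
incidence-driven lift), not a claim of viscous fidelity.

### Navier–Stokes solver

`ib_flow_init()`/`ib_flow_step()` implement a two-dimensional incompressible
solver on a staggered MAC grid: explicit advection–diffusion predictor,
multidirect immersed-boundary forcing (three sweeps of regularized
interpolation/spreading over Lagrangian markers carrying the plate velocity),
and a pressure projection solved by a sparse Cholesky factorization of the
Poisson operator. Inflow/far-field boundaries impose the freestream; the
outflow is convective with a pressure reference. The reaction to the
immersed-boundary forcing gives the fluid load on the plate, returned both
per marker and as a body total.

Verification: a Taylor–Green vortex on the companion spectral solver
(`spectral_flow_init()`) decays at the analytic rate $e^{-4\nu t}$ to six
digits; the immersed-boundary solver preserves a uniform stream through
moving markers to $10^{-10}$; discrete divergence is at round-off; a plate
aligned with the stream carries drag but no lift.

`rbf_deform()`/`deform_mesh()` provide radial-basis-function mesh deformation
(Wendland C2 kernel plus a linear polynomial, so affine motions are
reproduced exactly) with inversion detection through signed cell areas;
`compute_loads()` integrates pressure and viscous tractions over a surface;
`write_vtk_snapshot()` writes legacy-VTK fields for inspection.

## 6. Partitioned coupling

Each time step solves a fixed-point problem between the Newmark structural
step and the load provider evaluated on the resulting kinematics
(`coupled_step()`). Convergence is accelerated by Aitken $\Delta^2$ dynamic
relaxation on the free displacements (`aitken_solve()`), started at
$\omega_0 = 0.5$; the iteration stops when the displacement update drops
below `tol_w` ($10^{-6}$ m-scaled by default). For light, thin wings in air
the added-mass feedback is strong enough that plain iteration can diverge;
Aitken recovers the optimal relaxation factor automatically.

`run_cycles()` advances a configured case over full flapping cycles and
returns an `aeroelastic_solution` whose time series contain the plunge,
tip deflection, passive pitch, solver- and flight-frame forces, the
leading-edge reaction, and the inner-iteration counts; a periodicity
metric compares the last two cycles.

Verification: the partitioned scheme matches a monolithic Newmark solve of
the same linear added-mass problem to $10^{-8}$; a $10^6\times$ stiffer wing
follows the base motion rigidly with vanishing pitch; halving the coupling
tolerance changes mean lift by less than 0.5%.

## 7. Cycle performance and the power identity

`cycle_performance()` reduces a solution to cycle averages over the last
(periodic) cycle: mean lift and thrust, their coefficients (referenced to
$\tfrac12\rho V^2\, S$), aerodynamic and inertial actuator power, propulsive
efficiency $\eta = \bar L\, \overline{|\dot\zeta|} / \bar P$, and the
first-harmonic effective angle of attack.

The instantaneous actuator power obeys a discrete identity that the package
enforces to round-off: with the Newmark state satisfying
$M a + K d = f$ on the free degrees of freedom,

$$P(t) = 2R\, F_\mathrm{reaction}(t)\, \dot\zeta(t)
       = \underbrace{2R\, \mathbf{v}_r^\top M \mathbf{a}}_{P_\mathrm{inertial}}
       \; - \; \underbrace{(-2R\, \mathbf{v}_r^\top \mathbf{f})}_{-P_\mathrm{aero}},$$

where $\mathbf{v}_r$ is the rigid-plunge velocity pattern (and
$K\mathbf{v}_r = 0$). Hence $P = P_\mathrm{aero} + P_\mathrm{inertial}$
exactly at every step, and the cycle-mean inertial power vanishes for rigid
plunge. Aerodynamic power scales linearly with air density while inertial
power is density-independent — the mechanism behind the altitude trends in
the design study.

## 8. Synthetic data

`gen_force_deflection()` produces bench-like force–deflection records from
the beam model plus a calibrated noise model
(`measurement_noise_model()`): multiplicative force noise (10% spanwise,
32% chordwise, reflecting the much smaller chordwise forces) and a
log-normal specimen-to-specimen stiffness scatter (8% in log). Defaults
are the study conditions. `gen_flight_observations()` produces
altitude–airspeed–Reynolds observations from a linearly decreasing airspeed
model with 5% noise. `oracle_loads()` exposes the quasi-steady oracle
directly for testing.

## 9. Design space and equilibrium selection

`sample_design_space()` samples $(\rho_\mathrm{air}, \beta, V)$ on a full
grid or by Latin hypercube; `evaluate_design_points()` runs the coupled
model at each point and records the cycle performance;
`train_surrogate()` fits a single-hidden-layer neural network (`nnet`,
45 sigmoid units, linear output, weight decay $10^{-4}$, standardized
inputs/outputs, seeded for reproducibility) to all outputs jointly.

`fit_re_polynomial()` fits $\mathrm{Re}(h)$ as a quadratic to flight
observations. `select_equilibrium()` then searches, at each altitude, a
$101\times101$ grid over $(\beta, V)$ (with one local refinement pass) for
points where

* cycle-mean lift balances the weight target within tolerance
  ($5\ \mathrm{mN} \pm 0.1\ \mathrm{mN}$ by default), and
* the Reynolds number $\rho V c/\mu$ lies within 10% of the fitted
  $\mathrm{Re}(h)$,

choosing the feasible point closest to the lift target. The resulting
branch exhibits the characteristic altitude trends: airspeed falls,
stroke-plane angle and lift coefficient rise, and total actuator power
falls with altitude, driven almost entirely by the aerodynamic component —
the inertial component is nearly constant because it does not depend on
density. Because the selection is a grid search, reported optima are
quantized at the grid resolution.

## 10. Pipeline and command line

`run_config()` builds a validated configuration (optionally from YAML via
`read_run_config()`); `run_characterize()`, `run_simulate()` and
`run_altitude_sweep()` execute the three stages and write JSON/CSV artifacts
plus manifests recording the configuration and package version. The script
in `inst/cli/flapfsi.R` exposes the same three stages as `characterize`,
`simulate` and `sweep` subcommands.

## 11. Limitations

* The structural model is a linear chordwise beam: no spanwise bending,
  twist, or geometric nonlinearity, so large tip rotations are only
  indicative.
* The quasi-steady oracle has no wake memory or leading-edge-vortex
  dynamics; the Navier–Stokes path is two-dimensional and laminar, at
  desk-scale resolutions.
* The atmosphere model stops at the tropopause and uses a constant
  viscosity.
* Surrogate predictions are only trustworthy inside the sampled ranges;
  `select_equilibrium()` does not extrapolate.
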