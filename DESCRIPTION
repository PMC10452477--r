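Package: flapfsi
Title: Aeroelastic Analysis of Chordwise-Flexible Flapping Wings Across Altitude
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fluid-structure interaction of insect-scale
    chordwise-flexible flapping wings under varying air density (altitude).
    Includes reduction of force-deflection measurements to effective elastic
    moduli by inverse finite-element calibration, an Euler-Bernoulli beam
    finite-element solver with prescribed leading-edge plunge, a two-dimensional
    incompressible Navier-Stokes solver with an immersed moving plate, a
    partitioned fluid-structure coupling scheme with Aitken dynamic relaxation,
    a fast quasi-steady aerodynamic load model for desk-scale runs,
    cycle-averaged performance metrics (lift, thrust, aerodynamic and inertial
    power, propulsive efficiency, effective angle of attack), and a
    surrogate-assisted design-space sweep that selects equilibrium flight
    conditions (lift balancing weight at the observed Reynolds number) as a
    function of altitude.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    nnet,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
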