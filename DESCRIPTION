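Package: caclear
Title: Calcium Clearance Kinetics of Plasma-Membrane Calcium Pump Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models millisecond-scale clearance of cytosolic free calcium by
    plasma-membrane Ca2+-ATPase (PMCA) pump complexes in a spherical cell.
    Solves the stationary diffusion problem with a pipette-clamped calcium
    source and Hill-type pump efflux, and the dynamic reaction-diffusion
    problem with EGTA buffering and pulsed influx through voltage-gated
    calcium channels. A ten-state Ca2+- and voltage-dependent gating model of
    the large-conductance BK channel serves as the membrane-local calcium
    readout; Boltzmann and mono-exponential fitting utilities, calibration
    routines, a synthetic-data generator and composed in-silico experiments
    allow pump cycle rates to be inferred from activation-curve shifts and
    current-decay time constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    Matrix,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
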