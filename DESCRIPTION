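Package: marzss
Title: Echo-Time-Independent Metabolite T2 Relaxometry via RF-Driven
    Longitudinal Steady States
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and estimation tools for measuring metabolite
    transverse relaxation times (T2) in vivo without varying the echo time.
    A train of interleaved radio-frequency and gradient pulses drives
    longitudinal magnetization into a T1/T2-weighted steady state; fitted
    signal amplitudes acquired at several flip angles are converted into a
    linear regression whose slope gives sqrt(T1/T2), so that T2 follows from
    a separately measured T1. The package provides the closed-form
    steady-state model and its regression estimator, a Bloch-equation
    simulator of the pulse train (minimum repetition-time design), a
    density-matrix simulator of J-coupled metabolite spin systems under a
    PRESS readout (basis-set generation), a synthetic multi-flip-angle study
    generator with an unsuppressed water reference, linear-combination
    spectral fitting with spline baselines, inversion-recovery T1 fitting,
    and Monte Carlo tools for acquisition-protocol optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    splines,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
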