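Package: charAP
Title: Simulation and Analysis of the Characean Action Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the action potential (AP) of characean giant cells
    (Nitellopsis obtusa, Chara australis) with an IP3-gated four-state
    calcium-store channel model coupled to a plasma-membrane voltage
    equation carrying five currents: a Ca2+-activated chloride current, an
    Eyring-barrier proton pump, a Goldman-Hodgkin-Katz K+ outward rectifier
    with Boltzmann gating, an ohmic background current, and a transient
    TRP-like Ca2+ pulse.  Ships the published fitted parameter columns for
    freshwater, sorbitol and saline conditions as a bundled registry,
    computes zero-current resting potentials, extracts AP features from
    membrane-potential traces, averages trace ensembles with standard
    deviation bands, isolates the tonoplast AP component by subtraction
    with error propagation, fits model parameters to traces by bounded
    least squares, and generates synthetic current-clamp recordings with
    cell-to-cell parameter variability and measurement noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
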