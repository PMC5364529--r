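Package: uchfold
Title: Folding Kinetics, Stability and Binding Thermodynamics of Knotted
    Deubiquitinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for protein-folding studies of the
    UCH family of knotted deubiquitinases. Implements singular value
    decomposition of denaturant-titration spectra with autocorrelation-based
    component counting, global two-state equilibrium unfolding fits (linear
    extrapolation model), multi-exponential stopped-flow trace fitting with
    F-test phase selection, chevron-plot analysis with derived unfolding
    thermodynamics, double-jump interrupted-refolding analysis including
    linear three-state model inference, NMR hydrogen-deuterium exchange
    protection factors via the Bai-Englander intrinsic-rate model, two-state
    thermal denaturation fits, one-site isothermal titration calorimetry
    fitting with variable-temperature heat-capacity analysis, and relative
    contact order from atomic coordinates. A seeded synthetic-data generator
    emulates every input class so all analyses are testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    seqinr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
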