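Package: bandratchet
Title: Mechanical-Ratchet Model of Unilateral Cytokinesis and In Vivo
    Cytoplasmic Microrheology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying unilateral cytokinesis in large embryonic
    cells, where an open-ended contractile actomyosin band ingresses from one
    side of the cell. Implements a viscoelastic spherical-mesh simulator of a
    growing contractile band (Jeffreys-material edges, alternating
    interphase/M-phase mechanics, force-balance relaxation), closed-form
    Jeffreys and fractional Kelvin-Voigt rheology with creep-compliance to
    complex-modulus conversion, a magnetic-tweezers pulse-analysis pipeline
    (force calibration, drift correction, per-pulse summaries, weighted Welch
    tests and weighted bootstrap), laser-ablation recoil and band-kinematics
    analysis, and seeded synthetic-data generators emulating every input so
    the full analysis runs without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
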