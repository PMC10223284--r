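Package: pfastk
Title: In Vitro Toxicokinetics and IVIVE Dosimetry for Data-Poor PFAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vitro toxicokinetic assays of per- and
    polyfluoroalkyl substances (PFAS) measured by gas chromatography-mass
    spectrometry: weighted calibration-curve fitting with back-calculation
    accuracy checks and estimated method detection/quantitation limits,
    fraction unbound in plasma from ultracentrifugation assays with a
    plasma-stability screen, hepatocyte intrinsic clearance from
    substrate-depletion regressions with background (abiotic) adjustment,
    hierarchical Bayesian measurement-error models for credible intervals
    on fraction unbound and intrinsic clearance, and in vitro-in vivo
    extrapolation (IVIVE) to steady-state plasma concentration and
    administered equivalent dose. Includes a synthetic-data generator that
    emulates the assay designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
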