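Package: dlscreen
Title: Dynamic Ligation Screening Analysis for Fluorescence Anisotropy
    Fragment Screens
Version: 0.1.0
Authors@R:
    person("dlscreen", "developers", email = "dlscreen@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of dynamic-ligation (acylhydrazone
    exchange) fragment screens read out by fluorescence anisotropy against a
    PDZ domain. Implements plate-reader polarization channel processing,
    ligand-depletion direct binding and exact ternary competition equilibria,
    sigmoidal logistic IC50 fitting, mean-minus-3-sigma dual-threshold hit
    calling for duplicate screens, relaxed rule-of-three fragment-library
    curation with fingerprint diversity pruning, first-order hydrazone
    exchange kinetics, single-site isothermal titration calorimetry
    simulation and fitting, and seeded synthetic-data generators that emulate
    the full assay protocol so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
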