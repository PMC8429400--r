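Package: golgiph
Title: Golgi Resting pH: Electrochemistry, Anion-Exchange Kinetics, and
    Ratiometric pHluorin Quantification
Version: 0.1.0
Authors@R:
    person("golgiph", "developers", email = "golgiph@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the Golgi apparatus sets its luminal
    resting pH via bicarbonate-mediated net acid efflux. Provides Nernst
    equilibrium-potential calculations and a driving-force decomposition
    for electroneutral Cl-/HCO3- exchange; a kinetic simulator of Golgi
    luminal pH under V-ATPase pumping, passive proton leak, counter-ion
    chloride flux, AE2-type anion exchange and bicarbonate buffering; a
    quantification pipeline for ratiometric pHluorin imaging (sigmoidal
    calibration, ratio-to-pH inversion, initial-rate estimation,
    expression-binned regression, Gaussian-mixture subpopulation
    detection); a lectin-microarray differential fingerprint analysis
    (replicate aggregation, subtracted fingerprints, cross-pair
    intersection); and seeded synthetic-data generators for end-to-end
    testing without raw imaging or microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
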