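Package: welldose
Title: Predicting Chemical Exposure Concentrations in Multi-Well Plate Bioassays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Empirical and mechanistic models for the fraction of a dosed
    chemical that remains in the exposure medium of polystyrene multi-well
    plate bioassays. Implements a four-parameter sigmoid loss model driven by
    hydrophobicity (logKow) and volatility (log Henry's Law Constant), its
    nonlinear least-squares calibration with goodness-of-fit statistics,
    prediction bounds and repeated random-split cross-validation; equilibrium
    mass-balance and polystyrene-sorption baseline models; extrapolation of a
    calibrated cover model to other well-plate geometries; conversion of
    nominal EC50 values to exposure-corrected ones; and a seeded synthetic
    data generator for chemicals and loss observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
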