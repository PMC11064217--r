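Package: paleotp
Title: Sediment-Inferred Lake-Water Total Phosphorus Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs multi-century lake-water total phosphorus (TP)
    histories from dated sediment-core phosphorus records by steady-state
    mass-balance inversion (sediment-inferred TP, SI-TP): burial-flux
    computation, sediment-focusing correction, areal water-loading
    estimation, retention-coefficient anchoring against a monitored TP
    window, and a two-fraction (stable plus first-order-decaying labile)
    diagenesis correction for the stationary phosphorus peak in recent
    sediment. Includes penalized-spline smoothing of irregular records,
    proxy-proxy validation statistics against an independent diatom-inferred
    TP record (regression with confidence and prediction intervals,
    residual normality, peak timing, interval-weighted means), and a
    synthetic lake-sediment generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mgcv,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
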