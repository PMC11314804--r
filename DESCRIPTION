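Package: ramanbnf
Title: Estimating Biological Nitrogen Fixation from Leaf Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Chemometric workflow for quantifying biological nitrogen
    fixation (%BNF) in legumes from leaf Raman spectra. Provides spectral
    preprocessing (cosmic-ray despiking, Savitzky-Golay smoothing,
    iterative moving-average fluorescence baseline subtraction), partial
    least squares regression with leave-one-out cross-validation and
    VIP-based peak selection, and an elastic-net regularisation step whose
    penalty strength is tuned to minimise the predicted fixation of a
    non-fixing control set, making the calibration specific to nitrogen
    fixation rather than nitrogen availability. A synthetic-data generator
    emulating the fixing/non-fixing greenhouse design with isotope-dilution
    ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    glmnet,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
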