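Package: voccheese
Title: Chemometric Analysis of Volatile Profiles from X-Ray-Irradiated Cheeses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dose-discrimination studies of volatile organic compound
    (VOC) profiles measured by headspace solid-phase microextraction gas
    chromatography-mass spectrometry (HS-SPME/GC-MS). Covers the full workflow:
    linear retention indices by the van den Dool and Kratz formula,
    internal-standard normalization and feature-table assembly; face-centered
    central composite designs with second-order response-surface fits and
    Derringer desirability optimization of extraction conditions; principal
    component analysis with group confidence ellipses; NIPALS partial least
    squares discriminant analysis (PLS-DA) with variable-importance-in-projection
    (VIP) marker selection; double (nested) cross-validation with a full
    diagnostic panel (RMSECV, Q2, discriminant Q2, accuracy, sensitivity,
    specificity, efficiency, precision, Matthews correlation, AUROC); and
    permutation testing of misclassification counts against a binomial null.
    Includes a synthetic VOC-profile generator emulating dose-response structure
    of irradiated surface-ripened cheeses for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    mixOmics,
    optparse
Config/testthat/edition: 3
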