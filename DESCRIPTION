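Package: fibroscore
Title: Quantitative CT Densitometry and Visual Scoring of Interstitial
    Lung Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying interstitial lung disease on
    high-resolution computed tomography. Implements Hounsfield-unit
    threshold segmentation of the lungs, the computer-aided percent
    pulmonary fibrosis score (attenuation histogram over the
    -1024 to -200 HU lung window with a -700 HU normal-lung cut),
    the Warrick visual severity/extent score, cohort-level statistics
    (descriptives, group comparisons, Pearson correlation, multivariate
    regression with partial correlations, intraclass correlation and
    Bland-Altman agreement), and synthetic CT phantom and patient-cohort
    generators for end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    MASS,
    Matrix,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    tools,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
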