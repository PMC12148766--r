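Package: vent4d
Title: 4DCT-Based Lung Ventilation and Perfusion Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates and compares voxelwise lung-function images from
    respiration-correlated (4D) CT: the classical Hounsfield-unit
    density-change ventilation map, two robust subregional ventilation
    reconstructions (an integrated-Jacobian formulation based on hit-or-miss
    deformed-volume sampling, and a mass-conserving volume-change formulation
    based on density ratios), and a mass-change-magnitude perfusion surrogate.
    Includes an analytic deformable phantom generator with closed-form
    Jacobian ground truth, percentile functional contours with Dice overlap,
    dose-function metrics (functional mean lung dose and functional V20),
    binary reader-agreement summaries, and Friedman / Wilcoxon signed-rank
    statistics with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
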