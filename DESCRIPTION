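Package: hypoxmet
Title: Untargeted Metabolomics Discriminant Analysis with Double
    Cross-Validated PLS-DA and Permutation-Based Variable Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for two-class untargeted LC-MS metabolomics studies
    with small sample sizes: replicate collapsing, blank-based background
    removal and detection-frequency filtering of aligned feature tables;
    PCA with Q-residual and Hotelling's T-squared outlier statistics and
    Ward hierarchical clustering; PLS discriminant analysis fitted by
    NIPALS with discriminant Q-squared and misclassification-count figures
    of merit estimated by leave-one-out double cross-validation; model
    validation by an exhaustive non-complementary balanced label
    permutation test; permutation-null selection of differentiating
    features from the distribution of regression vectors; putative m/z
    annotation with adduct and in-source fragment rules; targeted MRM
    calibration, quantitation and identity-confirmation rules; and a
    seeded synthetic data generator emulating the study design for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
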