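Package: flavorlink
Title: Linking Sensory Panel Profiles to Untargeted Metabolomics Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A sensomics analysis toolkit that links trained-panel
    quantitative descriptive analysis (QDA) scores to untargeted LC-MS and
    GC-MS feature tables. Implements assessor-wise standardization and
    back-transformation of panel scores, mixed-ANOVA product-effect F
    statistics, post-peak-picking feature-table preprocessing (blank and
    QC-RSD filtering, log transform, technical-replicate averaging,
    autoscaling, PCA), NIPALS partial least squares with VIP ranking,
    random-forest permutation-importance ranking, and a repeated
    double cross-validation (rdCV) feature-elimination engine yielding
    minimal-optimal and all-relevant marker sets with balanced-accuracy or
    Q-squared performance estimates. A coupled synthetic-data generator
    emulates the full study structure (panel, dual MS platforms, QC and
    blank samples) with known ground truth for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
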