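Package: morphclass
Title: Nested Leave-One-Out SVM Feature Elimination for Brain Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies individuals from regional brain-volume features with a
    linear support vector machine wrapped in a nested leave-one-subject-out
    procedure: the outer loop estimates accuracy, the inner loop eliminates
    features ranked by absolute hyperplane coefficient and picks the feature
    count that maximises inner-loop accuracy. Includes per-fold covariate
    (age, sex) residualization and standardization fitted on training folds
    only, parsers for FreeSurfer aseg/aparc volume stats tables, consensus
    discriminative-region mapping, exact binomial significance of classifier
    accuracy, empirical ROC curves, and a synthetic two-group cohort
    generator with planted regional effects and demographic confounds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
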