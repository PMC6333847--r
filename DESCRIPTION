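Package: longconn
Title: Longitudinal Brain Connectome Progression Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes disease-progression scores from paired (baseline,
    year-1 follow-up) structural brain connectomes on a 16-region
    subcortical parcellation of the nigrostriatal pathway.  Per-subject
    longitudinal features are the element-wise absolute differences of
    upper-triangle connectome vectors for three connectivity metrics
    (streamline count, mean fractional anisotropy, mean diffusivity),
    concatenated into a 360-dimensional vector.  A sparse (L1-regularized)
    logistic regression trained under stratified k-fold cross-validation
    on Control and Parkinson's disease subjects yields out-of-fold
    progression scores, and model averaging over the fold models scores an
    independent prodromal cohort.  Includes a label-permutation null for
    classifier-weight relevance with a five-standard-deviation prominence
    rule, ROC/AUC evaluation with bootstrap percentile confidence
    intervals and a sensitivity^2+specificity^2-optimal threshold,
    covariate-adjusted significance, prodromal subtyping by the
    Control/PD-derived threshold, and a synthetic longitudinal cohort
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
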