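Package: symptomnet
Title: Depression Prevalence and PHQ-9 Symptom Network Analysis for Caregiver Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional survey studies of depression in
    caregiver populations: scoring of the PHQ-9, GAD-7, fatigue numeric
    rating scale and a two-item WHOQOL-BREF quality-of-life index;
    prevalence estimation with Wald confidence intervals; univariable
    group comparisons (pooled t, Wilcoxon rank-sum, Pearson chi-square);
    multiple logistic regression and ANCOVA; and regularized
    partial-correlation symptom networks estimated by graphical lasso
    with extended-BIC penalty selection on polychoric correlations,
    together with strength centrality, case-dropping stability bootstrap
    with the correlation-stability coefficient, edge-accuracy bootstrap,
    covariate-adjusted re-estimation, quality-of-life flow extraction and
    a permutation network comparison test. A latent-Gaussian threshold
    simulator generates ordinal survey cohorts with known sparse network
    structure for calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    pracma,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
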