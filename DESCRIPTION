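Package: ckdprog
Title: Time-Dependent Survival Models for Chronic Kidney Disease Progression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for modelling progression from chronic kidney disease (CKD)
    to dialysis using longitudinal clinic-visit data. Characterizes
    time-varying laboratory trajectories (per-visit variability slopes),
    encodes records in counting-process form, and fits three time-dependent
    survival models: a Cox proportional hazards model fitted by
    Newton-Raphson on the counting-process partial likelihood, a random
    survival forest grown with the log-rank split rule, and a pseudo-value
    multilayer-perceptron survival regression. Includes nonparametric
    estimators (Kaplan-Meier, Nelson-Aalen, jackknife pseudo-values,
    concordance index), cohort summary statistics, a synthetic longitudinal
    cohort generator emulating a stage 3-5 CKD study design, K-fold
    cross-validated evaluation with cut-off classification metrics,
    individual Kaplan-Meier validation, and permutation variable importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
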