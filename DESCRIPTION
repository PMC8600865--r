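Package: radsens
Title: Radio-Sensitive Gene Discovery from Expression and Survival Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An interaction-model pipeline for screening genes whose
    median-dichotomized expression predicts discrepant overall-survival
    benefit from radiotherapy. Implements cohort eligibility filtering,
    a dataset-level radiotherapy-protective screen, chained-equation
    multiple imputation of clinical covariates with imputation stacking
    and weighted Cox fitting, AIC fast-backward covariate selection,
    scenario-based classification of radio-sensitive genes (Type I and
    Type II, by high- or low-expression benefit group), hierarchical
    clustering of patients on the resulting gene panels, and a synthetic
    cohort generator with planted gene-by-treatment interactions for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
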