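Package: depcompare
Title: Comparing Gene-Dependency Screens Across Perturbation Modalities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing genome-scale loss-of-function screens performed
    with different perturbation modalities (knockout-like versus knockdown-like),
    in the style of Cancer Dependency Map analyses. Provides screen quality
    control (SSMD, control ROC AUC, reagent concordance, control-anchored
    scaling), dependency classification (rank-based pan-dependency calling with
    bimodal thresholding, kernel-density posterior probability of dependency,
    skew-t likelihood-ratio selectivity, high-variance calling, and a
    priority-ordered class assignment), cross-dataset agreement and
    high-confidence gene sets, random-forest biomarker modeling with
    rule-based predictive-marker classes, dose-level drug-dependency
    association with principal-component confound removal, and co-dependency
    network construction with similarity network fusion. Includes a synthetic
    screen generator with planted ground truth for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    digest,
    pROC,
    ranger
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
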