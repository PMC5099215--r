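Package: grseval
Title: Evaluation of Genetic Risk Scores Added to Phenotypic
    Cardiovascular Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to construct weighted and unweighted polygenic risk
    scores from allele dosages, combine them with a phenotypic 10-year
    cardiovascular risk probability on the logit scale, and evaluate the
    combined score: sampling-weighted AUROC and detection rate at fixed
    false-positive rate, Hosmer-Lemeshow decile calibration with
    follow-up rescaling, weighted net reclassification improvement with
    nested case-control control upweighting, fixed- and random-effects
    meta-analytic combination across studies, and a two-stage screening
    strategy for the intermediate-risk band with number needed to
    screen. Includes a multi-study synthetic cohort simulator (Hardy-
    Weinberg genotypes, logit-additive event model, nested case-control
    subsampling) so every stage is testable without access to
    individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr
Config/testthat/edition: 3
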