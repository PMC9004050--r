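Package: llindur
Title: Durability, Attrition and Bayesian Survival Analysis of Long-Lasting Insecticidal Net Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the physical durability of long-lasting
    insecticidal nets (LLINs) followed as a post-distribution cohort.
    Implements proportionate hole index (pHI) scoring and WHO condition
    classes, reorganisation of round-by-round observations into a monotone
    nets-by-rounds status matrix with explicit unknown cells, reason-for-
    absence breakdowns, survival and retention rates with Wilson confidence
    intervals, median survival time by linear interpolation, and a Bayesian
    discrete-time survival model with household random effects fitted by
    Gibbs sampling with data augmentation of ambiguous net statuses. A
    synthetic cohort generator with a true-parameter manifest supports
    end-to-end testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
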