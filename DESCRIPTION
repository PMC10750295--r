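Package: subtyperx
Title: Subtype-Stratified Drug Specificity Screening and Signature
    Scoring for Breast Cancer Cell-Line Panels
Version: 0.1.0
Authors@R: person("subtyperx", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools to screen cell-line drug-response panels for breast-cancer
    subtype-specific agents (per-drug one-way ANOVA with Tukey HSD post-hoc and
    a lowest-mean specificity rule on IC50 z-scores), to compute formula-defined
    gene-set activity scores on expression matrices (sum-of-z signature scores
    such as YAP/TAZ target and focal-adhesion scores, raw-sum scores such as the
    CLDN score), to associate scores with drug sensitivity and survival
    (correlation with regression line, mutation-stratified regression,
    median-split log-rank comparison), to quantify drug-combination synergy by
    the Chou-Talalay median-effect combination index, and to apply small
    experimental quantification formulas (blot-derived activated signal,
    percent-of-control viability, caliper tumor volume). A synthetic-data module
    generates every input shape with planted ground truth so the whole pipeline
    is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
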