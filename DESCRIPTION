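Package: ctrank
Title: Rank-Order Differential Expression for TaqMan qPCR miRNA Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis of censored cycle-threshold
    (Ct) matrices from low-density TaqMan miRNA arrays. Implements
    within-sample force ranking with an unequal-variance t-test on ranks,
    median and endogenous-control normalization with geNorm-style M-value
    stability selection, an empirical-Bayes moderated t-test,
    delta-delta-Ct fold changes and calibrated relative expression,
    rank-rank regression with prediction-interval outlier calls,
    automated amplification-kinetics curation, and a cross-species
    conserved/expressed miRNA target consensus with right-tailed Fisher
    gene-set enrichment. Includes a seeded simulator of arrays,
    amplification curves and target-prediction fixtures with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    knitr,
    limma,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
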