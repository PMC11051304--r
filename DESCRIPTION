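Package: dmrvote
Title: Differentially Methylated Region Detection by Beta-Binomial
    Empirical Bayes Estimation and Rank-Vote Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differentially methylated regions (DMRs) in
    bisulfite-sequencing count data from two groups of replicates.
    Per-CpG methylation means and dispersions are estimated under a
    beta-binomial hierarchical model with an empirical-Bayes log-normal
    prior on the dispersion; CpG sites are then scored by an ensemble of
    three ranking statistics (Fisher ratio, Z-score, Welch's t), merged
    by a normalized-rank voting rule, and segmented into
    direction-consistent regions whose member p-values are combined by
    Fisher's method with Benjamini-Hochberg FDR control.  Ships a
    ground-truth RRBS-like simulator and a region-level evaluation
    harness (confusion metrics and ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
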