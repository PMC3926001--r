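Package: medipewas
Title: Twin-Based MeDIP-Seq Epigenome-Wide Association Analysis of Pain Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies of quantitative
    traits from MeDIP-seq data in twin designs. Quantifies methylation as
    relative methylation quantification (RMQ) scores in overlapping 1-kb
    bins, fits per-bin linear mixed models in monozygotic twin pairs and
    ordinary linear models in unrelated cohorts, estimates genome-wide
    significance thresholds by family-preserving permutation FDR, combines
    cohorts by inverse-variance fixed-effect meta-analysis with Cochran's Q
    and I-squared heterogeneity filtering, calls allele-specific methylation
    from allelic read counts, and provides follow-up analyses (cis-meQTL
    scans, white-blood-cell composition checks, longitudinal stability
    classification, blood-brain tissue sharing, and cross-platform direction
    validation). A synthetic-data generator reproduces the statistical
    structure of a discordant-twin pain-sensitivity study at desk scale so
    the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    lme4,
    metafor,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
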