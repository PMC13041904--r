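Package: scqtl
Title: Pseudo-Bulk and Dynamic Single-Cell eQTL Mapping with
    Cross-Cell-Type Effect Sharing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A statistical toolchain for cell-type-resolved expression
    quantitative trait locus (eQTL) analysis of single-cell cohorts:
    pseudo-bulk aggregation with the standard donor/cell qualification
    filters, per-cell-type cis-eQTL mapping with a permutation/Beta
    approximation scheme and Storey q-value eGene calling, empirical-Bayes
    harmonization of effects across cell types with local false sign
    rates and sharing classification, functional annotation enrichment of
    eQTL SNPs against chromatin-state and ATAC-peak tracks,
    cell-state-interacting (dynamic) eQTL modelling along a pseudotime
    trajectory with a negative-binomial mixed-effects model, and GWAS
    integration by approximate-Bayes-factor colocalization and
    transcriptome-wide association (TWAS). Includes a synthetic-cohort
    generator with ground-truth effect records for calibration and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    glmnet,
    GenomicRanges,
    IRanges,
    vcfR,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
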