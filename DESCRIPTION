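Package: errg
Title: Enhancer RNA Regulated Gene Identification and Multi-Omics Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies enhancer RNA (eRNA) regulated genes by building
    fixed-width eRNA regions around enhancer midpoints, discarding regions
    that overlap annotated genes, assigning genes that fall within a
    contact-domain window around each eRNA, and intersecting the
    assignments across several enhancer resources. Downstream two-group
    analyses cover expression mean and coefficient-of-variation contrasts
    against size-matched random gene sets, differential-expression
    thresholding with a resampling null, differential methylation on
    beta-value matrices, differential and co-occurring somatic mutations,
    and a gene-signature risk-score median split compared by Kaplan-Meier
    and log-rank statistics. A synthetic-data generator with planted
    ground truth makes the whole pipeline testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
biocViews: GeneRegulation, Epigenetics, Survival, StatisticalMethod
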