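Package: methylotype
Title: Consensus DNA Methylation Subtyping of Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive and transfer DNA methylation subtypes of tumors
    from Illumina 450K-style beta-value matrices. Implements peak-based
    correction of the type I/II assay chemistries, k-nearest-neighbour
    imputation, derivation of tumor-methylated and tumor-demethylated CpG
    sets against a normal-cell reference, bootstrap consensus hierarchical
    clustering into methylation subtypes, nearest-centroid classification of
    external cohorts, and downstream subtype statistics (region-set
    methylation summaries, expression signature scores, association tests and
    survival comparisons). A seeded synthetic-cohort generator emulating
    promoter-island hypermethylation, heterochromatin demethylation and
    leukocyte admixture supports testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    limma,
    data.table,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
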