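Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling and Prognostic Marker
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for SAGE-style digital gene expression
    (DGE) tag profiling of paired tumor/normal libraries and for
    immunohistochemistry-driven survival analysis. Builds a virtual
    NlaIII restriction-tag catalog (CATG plus 17 bp) from a genome,
    maps observed 21-bp tags with at most one mismatch, normalizes to
    tags per million, tests per-patient differential expression with
    the Audic-Claverie exact test plus Benjamini-Hochberg false
    discovery control, aggregates recurrently deregulated genes across
    a cohort, compares gene lists between cohorts (hypergeometric
    overlap, average-linkage clustering with the uncentered Pearson
    metric), and fits Kaplan-Meier, log-rank and Cox
    proportional-hazards models on staining-index dichotomized
    markers. Includes seeded synthetic-data generators for genomes,
    tag libraries, paired count studies and clinical cohorts so the
    whole pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
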