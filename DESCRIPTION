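Package: circflow
Title: Circular RNA Discovery, Coding-Potential and Downstream Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable dry-lab pipeline for circular RNA (circRNA) biomarker
    discovery from probe-by-sample expression cohorts: abundance filtering and
    two-group differential expression, a from-scratch weighted co-expression
    network core (soft-threshold scan, topological overlap, module detection,
    eigengenes, module-trait association), ReliefF hub-probe screening with
    unsupervised sample clustering, circular open-reading-frame prediction
    across the back-splice junction including rolling-circle ORFs and IRES
    annotation, junction-unique tryptic peptide derivation, exon-skipping and
    other alternative-splicing quantification (PSI) with differential testing
    and RIP-target intersection, Kaplan-Meier/log-rank survival stratification
    and hypergeometric over-representation analysis. Seeded synthetic-data
    generators emulate the statistical structure of the multiple-myeloma
    microarray cohorts the pipeline was designed around, so every stage is
    exercisable and testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
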