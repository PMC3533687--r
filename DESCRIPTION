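Package: pgcmeth
Title: Simulation and Analysis of DNA Methylation Reprogramming in
    Primordial Germ Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying genome-wide DNA methylation erasure in
    mouse primordial germ cells (PGCs) from synthetic bisulfite-sequencing
    data. Provides a seeded generator of genome annotations, per-stage
    cytosine call tables, hairpin bisulfite reads and expression
    time-courses; tiling-probe and feature-level methylation
    quantification with bisulfite conversion control; classification of
    late-demethylating, demethylation-resistant and variably erased CpG
    islands including IAP-proximity effects; hairpin dyad-state analysis
    with passive and active demethylation null simulations; a
    replication-dilution model of maintenance, de novo and active
    demethylation with maximum-likelihood parameter recovery; and
    expression-complexity and time-course clustering summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
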