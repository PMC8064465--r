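Package: varprior
Title: Integrative Variant Prioritization for a Single Gene
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative variant-prioritization workflow for a single
    gene. Computes per-residue conservation and codon-usage selection
    scores from an in-frame codon alignment, 21-codon sliding-window
    conservation, and conserved-motif calls; converts categorical effect
    predictor annotations (PolyPhen2, Provean, SIFT, align-GVGD) plus the
    evolutionary residue score into an additive variant score (maximum 6)
    and a combined impact score weighted by window conservation and
    population allele frequency; scores noncoding variants by summed
    regulatory-evidence overlaps multiplied by CADD with per-LD-block
    reduction; and computes rare-disease-cohort carrier-frequency
    enrichment over population allele frequencies. A seeded synthetic-data
    generator provides alignments with planted conserved motifs and
    synonymous-wobble columns, variant tables, peak tracks, and cohorts
    with planted enrichment, so every stage is testable against known
    ground truth without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
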