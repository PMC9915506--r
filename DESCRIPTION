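Package: condelscreen
Title: Comparative Genomic Screening for Recurrently Deleted Conserved Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genomic intervals that are conserved across
    trait-complete outgroup species but deleted in multiple independent
    trait-reduced lineages (CONDELs). Provides a parser and writer for UCSC
    pairwise alignment chains, genomic interval algebra, orthologous chain
    selection, chain-gap extraction with assembly-gap masking, sliding-window
    conservation scoring with a coverage-quota element caller, the gene-centric
    genotype-phenotype screen with violation accounting and genomic-context
    classification, exact 2x2 unconditional tests (Boschloo) and binomial term
    enrichment with false-discovery-rate control, plus a synthetic multi-species
    study generator with a known truth set for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
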