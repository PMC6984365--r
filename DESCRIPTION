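Package: lncevo
Title: Comparative Identification and Expression Evolution of Long Noncoding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A comparative-transcriptomics pipeline for studying long noncoding
    RNA (lncRNA) evolution across species, organs and developmental stages.
    Implements annotation filtering and lncRNA locus selection with a per-filter
    audit trail, codon-substitution-frequency (CSF) coding-potential scanning,
    chain-guided exon-block projection with reciprocal-best-hit orthology,
    rank-based scaling normalization of TPM matrices, negative-binomial
    developmental-stage differential expression, sequence-conservation
    aggregation over gene regions, an expression conservation index with
    bootstrap envelopes, and per-gene expression divergence decomposition.
    Includes a deterministic multi-species simulator (genomes, annotations,
    chain maps, conservation tracks, replicate expression) with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
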