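Package: nexuspipe
Title: ChIP-Nexus Analysis of Paired Corticosteroid Receptor Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, desk-testable pipeline for ChIP-nexus data from
    a dual transcription-factor system (mineralocorticoid and glucocorticoid
    receptors across hormone conditions): read quality filtering, random
    barcode extraction and PCR-duplicate removal, Poisson local-lambda
    enrichment peak calling with input normalization, gene-relative peak
    annotation, two-factor overlap and hormone-condition retention
    statistics, strand-specific lambda-exonuclease border-pair detection,
    midpoint-referenced co-positioning distributions, and known-motif PWM
    scanning around peak summits. A synthetic ChIP-nexus generator with
    planted binding sites and ground-truth tables makes every stage
    verifiable at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
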