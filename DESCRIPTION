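Package: epitet
Title: Tet Target Gene Discovery from ChIP-seq, hMeRIP-seq and RNA-seq Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative epigenomics pipeline that identifies Tet target
    genes by combining Tet DNA-binding peak calling from ChIP-seq style
    coverage, 5-hydroxymethylcytosine (5hmrC) RNA-modification peak calling
    from hMeRIP-seq style coverage, wild-type versus Tet-null reduction
    classification, and expression-level integration. Includes a
    local-background Poisson peak caller with replicate summit-window
    saturation analysis, genomic feature annotation and metagene profiling,
    transcript-element distributions for RNA peaks, a k-mer enrichment
    stand-in for de novo motif discovery, a negative-binomial differential
    expression stage, and a fully seeded synthetic-data generator with known
    ground truth so every stage is testable without external downloads.
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
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
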