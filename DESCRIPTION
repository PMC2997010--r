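Package: syntenyr
Title: Anchor-Based Synteny Block Detection and Analysis for Gene-Order Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects maximal synteny blocks between two gene-order genomes from
    an ortholog correspondence table, under configurable caps on in-map and
    out-map mismatches and coupled order/strandedness modes, with nested-block
    (segmental duplication) flagging. Includes downstream analytics (genomic
    coverage, block size statistics, chromosome distribution matrices,
    Mann-Whitney regional comparisons, random-breakage significance), operonic
    block classification, tandem expansion/contraction detection, a
    synteny-guided annotation-refinement decision engine, and a genome
    rearrangement simulator with planted ground truth for end-to-end
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    IRanges,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
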