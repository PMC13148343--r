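Package: epregulome
Title: Enhancer-Promoter Regulome Mapping from HiChIP Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the three-dimensional regulome of a motif-anchored
    transcription factor from HiChIP interaction calls. Provides
    position-weight-matrix scanning of loop anchors, promoter/intergenic anchor
    classification, enhancer-promoter pair construction with a per-gene summed
    contact-count statistic (sumCC), ROSE-style stitched and super-enhancer
    calling, motif-centered chromatin-state clustering, differential-expression
    integration, subtype-specificity filtering, bin-matched module scoring,
    preranked gene-set enrichment, and a stratum-adjusted correlation
    coefficient for replicate reproducibility. A seeded synthetic-data
    generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    methods,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
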