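Package: regmapr
Title: Region Calling, Enrichment and Gene Association for Reporter-Assay
    Regulatory Element Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of ChIP-enriched lentiviral massively
    parallel reporter assay (ChIP-lentiMPRA) libraries. Reconstructs cloned
    fragments from paired-end alignments, merges them into an RPM-filtered
    map of candidate regulatory regions, quantifies overlap of the map with
    chromatin feature tracks against size- and chromosome-matched random
    regions, associates regions with genes by GREAT-style basal-plus-extension
    regulatory domains, partitions genes into proximal/distal groups, and
    provides the accompanying rank-sum, composition and fold-enrichment
    statistics. Includes a deterministic synthetic-data generator with planted
    regulatory elements so the whole pipeline can be exercised and validated
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
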