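Package: bivalstate
Title: Chromatin Bivalency Calling, State Dynamics, and Expression Meta-Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for promoter-level analysis of chromatin bivalency from
    sequential (re-ChIP) and separate H3K4me3/H3K27me3 ChIP-seq peak sets:
    bona fide bivalent-promoter calling by sequential/separate intersection,
    quantitative differential marking via M-A normalization and an exact
    conditional count test, three-state bivalency classification (H3K4me3-high,
    H3K27me3-high, equal) with transition tracking coupled to expression
    change, transcription-factor co-occupancy at bivalent promoters, and
    recurrent-NMF expression meta-program identification with Jaccard
    clustering. Includes a synthetic-data generator with planted truth so the
    whole pipeline can be exercised and validated without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
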