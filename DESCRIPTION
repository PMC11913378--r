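Package: tadloops
Title: TAD-Boundary Gene Pairs and p300/H3K27me3 Repressive Loop Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for super-enhancer and TAD-boundary gene
    regulation. Derives p300-only peaks (p300 ChIP-seq peaks free of
    extended H3K27ac), annotates genomic feature distributions of peak
    sets, classifies chromatin-loop and TAD-boundary interaction
    categories including repressive p300-only/H3K27me3 loops, computes
    virtual 4C profiles and aggregate peak analysis (APA) with VC_SQRT
    balancing on binned Hi-C contact matrices, screens TADs for
    head-to-tail boundary gene pairs with oncogene and promoter-mutation
    cross-referencing, compares expression between interaction classes,
    and performs delta-delta-Ct qPCR quantification. A seeded synthetic
    data module generates every input type with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
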