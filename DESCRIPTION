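Package: exoBorders
Title: Border-Pair Detection for ChIP-exo Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls transcription-factor binding-site boundaries from ChIP-exo
    sequencing data. Strand-separated 5'-end coverage tracks are depth
    normalized (with optional k-mer composition bias correction estimated from
    singleton reads), biological replicates are consolidated with a Shannon
    relative-entropy weight, single-nucleotide border peaks are detected per
    strand with a Chebyshev-inequality outlier statistic against a local
    background, and forward/reverse borders are matched into border pairs with
    the Gale-Shapley stable-matching algorithm, scored by a Gaussian kernel
    around the expected pair size (fitted by Gaussian-mixture EM) and a
    Fisher-combined p-value. A deterministic read simulator with known border
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    methods,
    GenomicRanges
Imports:
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
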