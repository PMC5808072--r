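Package: lamingate
Title: Somatic Hypermutation Quantification and Lamin B1 Domain Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies somatic hypermutation (SHM) in immunoglobulin
    V-region clone sets from Sanger-style sequencing: global alignment
    against the reference amplicon, substitution calling, AID hotspot
    (WRCY/RGYW) classification, mutations-per-base-pair statistics with a
    minimum-coverage rule, and exact conditional rate-ratio tests between
    experimental conditions. Calls Lamin B1 lamina-associated domains
    (LADs) from depth-matched ChIP/input binned count tracks by log-ratio
    discretisation and all-maximal-scoring-segment detection with
    permutation significance, and compares conditions via per-chromosome
    binding profiles, canyon/mesa detection, annotation overlap with
    circular-permutation nulls, and locus-level fold changes. A synthetic
    data module generates clone sets under an AID-biased mutation model
    and ChIP/input tracks with planted domains, so the whole pipeline is
    reproducible from seeds alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    withr,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
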