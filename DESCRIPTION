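Package: apmsflow
Title: AP-MS Interactor Discovery and Genomic Co-Localization Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for affinity-purification mass
    spectrometry (AP-MS) interactor discovery: construction of concatenated
    target/contaminant/reversed-decoy protein search databases, class-specific
    target-decoy filtering of peptide-spectrum matches at a requested peptide
    false discovery rate, parsimonious protein inference with a two-peptide
    rule, spectral counting with proportional splitting of shared-peptide
    counts, and a beta-binomial likelihood-ratio test (with Benjamini-Hochberg
    adjustment) that calls bait interactors against pooled controls and
    classifies treatment effects after bait normalization.  A companion set of
    genomic interval statistics (merge, coverage fractions, Jaccard and
    projection tests, absolute/relative midpoint-distance ECDF correlations
    with permutation nulls, chromatin-state annotation) supports comparison of
    ChIP-derived binding-site sets.  A deterministic synthetic-data generator
    produces every input the pipeline consumes, so all stages run with no
    external downloads.
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
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
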