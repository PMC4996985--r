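Package: amdscreen
Title: Sequence-Based Screening and Classification of Arylmalonate
    Decarboxylases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate arylmalonate decarboxylases (AMDases,
    EC 4.1.1.76) in protein sequence collections and separates them from
    the closely related racemases of the aspartate/glutamate racemase
    superfamily. Implements a pairwise-identity/E-value pre-filter, a
    reference-anchored twelve-criterion catalytic-motif filter, a
    six-pattern degenerate motif engine, a profile hidden Markov model
    scorer with sequence-logo export, and a classifier that assigns
    candidates to eight enzyme clusters from phylogenetic distance and
    gene-neighborhood transporter content. Ships a deterministic
    synthetic-data generator for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
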