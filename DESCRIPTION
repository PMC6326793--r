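Package: utrcode
Title: Combinatorial 3'-UTR Code for Maternal mRNA Translational Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cis-regulatory elements (polyadenylation signals,
    cytoplasmic polyadenylation elements and Pumilio-binding elements) in
    mRNA 3'-UTRs and predicts stage-specific translational behaviour of
    maternal transcripts in mouse oocytes from the spatial arrangement of
    those elements. Each polyadenylation signal is classified by its CPE
    context (free, one-sided or flanked) with calibrated distance windows,
    giving per-stage relative activities (germinal-vesicle stage versus
    after germinal vesicle breakdown) and a transcript fate class. Includes
    an in-silico reporter mutagenesis toolkit (element mutation, spacer
    deletion, CPE insertion, distal truncation), a seeded generator of
    motif-controlled synthetic 3'-UTRs with packaged Cpeb1-, Btg4- and
    Cnot6l-like architectures, and a validation harness that scores
    predictions against the observed reporter-assay outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
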