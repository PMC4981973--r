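Package: trnaOrtho
Title: Synteny-Based Orthology and Evolutionary Event Inference for
    Concertedly Evolving Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs orthology relations and duplication, gain, loss and
    anticodon-remolding histories for multicopy gene families that evolve under
    concerted evolution, with tRNAs as the motivating case.  Because concerted
    evolution keeps paralogous copies nearly identical in sequence, orthology is
    inferred from syntenic anchors (alignment blocks or orthologous proteins)
    instead of sequence divergence: a candidate homology graph built from tight
    anchor pairs is pruned by sequence distance, refined by duplication-aware
    list alignment of gene clusters, and corrected to cographs whose cotrees
    expose duplication events.  Gains and losses are mapped onto a species tree
    by Dollo parsimony, and anticodon remolding events are detected and
    classified as iso- or alloacceptor changes.  A forward simulator of gene
    cluster evolution with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    igraph,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
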