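Package: piclust
Title: Comparative Identification and Evolutionary Analysis of piRNA Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to identify germline piRNA clusters from small-RNA
    alignments, profile their transposon landscape and sequence divergence,
    trace cluster loci across related species by flanking-gene synteny,
    quantify inversion-breakpoint enrichment at cluster flanks with a
    signed-permutation z-score, attribute transposon-family piRNAs to their
    source clusters, and model chromosomal cluster deletions in silico.
    Includes a multi-species synthetic data generator with planted clusters,
    inversions and small-RNA reads so the whole pipeline can be exercised
    with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
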