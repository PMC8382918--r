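Package: htte
Title: Detection of Horizontal Transfer of Transposable Elements from
    Low-Depth Sample Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to detect horizontal transfer (HT) of transposable
    elements, in particular LTR-retrotransposons, between diverged plant
    lineages using low-depth unassembled shotgun ("sample") sequences.
    Implements a targeted screen seeded by reverse-transcriptase domain
    reads, a nontargeted whole-genome screen based on densely mapped
    read regions, divergence calibration against coding sequences,
    similarity clustering and minimum HT-event accounting, direction
    inference by phylogenetic nesting, UPGMA-based activity-history
    reconstruction, and insertion-junction verification (terminal
    TG...CA motifs and target-site duplications). A synthetic-data
    generator produces diverging genome pairs with planted transfers so
    the whole pipeline can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
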