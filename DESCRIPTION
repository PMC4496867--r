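Package: archintron
Title: Detection, Classification and Primer Auditing of Archaeal 16S rRNA
    Gene Introns
Version: 0.1.0
Authors@R: person("Zack", "Rivers", email = "zrivers@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing intron insertions in archaeal 16S rRNA
    genes of the kind found in thermophilic Crenarchaeota: structural
    detection of insertions against an intron-free reference coordinate
    frame (standard E. coli numbering), classification into
    homing-endonuclease, hairpin, remnant and partial/uncharacterized
    categories via open reading frame and LAGLI-DADG motif scanning,
    base-pair-maximization folding and bulge-helix-bulge junction
    detection, in-silico auditing of degenerate "universal" 16S primers
    for intron interruption, per-locus neighbor-joining phylogenies with
    bootstrap supports, and a fully seeded synthetic-data generator
    providing ground truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
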