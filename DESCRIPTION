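Package: concord
Title: Decisive Gene Counts, Congruence Frequencies, and Phylogenomic
    Supermatrix Bookkeeping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for summarizing the agreement between a set of
    incomplete, unrooted gene trees and a rooted reference species tree.
    For every clade of the reference, counts the gene trees whose taxon
    sampling makes them decisive for that clade (at least one taxon in
    each descendant cluster and at least two taxa basal to the node,
    minimally a quartet) and, among those, the fraction whose unrooted
    topology contains an edge separating the sampled clade members from
    the sampled outsiders (the congruence frequency). Also provides the
    bookkeeping used to assemble phylogenomic supermatrices: longest-ORF
    selection per locus, confidence-score column masking, orthogroup
    filtering, concatenation with partition and occupancy accounting,
    taxon-deletion pruning, and bootstrap clade-frequency summarization,
    together with a deterministic simulator of species trees, incomplete
    error-laden gene trees, and orthogroup alignments so that every
    stage can be verified on synthetic data.
License: MIT
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    Biostrings,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
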