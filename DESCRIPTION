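Package: msaclust
Title: Non-Progressive Multiple Sequence Alignment by Residue Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns protein or nucleotide sequence sets without a guide tree.
    Pairwise partition functions under affine gap penalties yield posterior
    residue-pairing probabilities, which are sharpened by an (optionally
    weighted) consistency transformation and assembled into a k-partite
    residue graph.  The graph is clustered into alignment columns by
    recursive, order-constrained, balance-bounded Fiduccia-Mattheyses
    bipartitioning (optionally multilevel), and the resulting alignment is
    polished by posterior-driven iterative refinement.  Includes a synthetic
    sequence-family simulator with known true alignments and sum-of-pairs /
    total-column scoring for evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    Matrix,
    methods,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
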