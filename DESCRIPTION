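Package: dcjsub
Title: Genomic Distance by Double-Cut-and-Join and Substitutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the exact genomic distance between two gene-order
    genomes with unequal marker content and no duplicated markers under a
    model that allows double-cut-and-join (DCJ) rearrangements together
    with substitutions of unique-marker blocks, a generalisation of
    insertions and deletions in which a deletion and an insertion at the
    same position count as a single step.  Provides the labeled adjacency
    graph machinery (runs of unique markers, indel and substitution
    potentials, singleton pairing, recombination-group deductions), a
    GRIMM-style gene-order parser, an operation engine for DCJs and
    substitutions, a seeded simulator that plants a known number of
    operations, and an independent brute-force oracle for validating the
    closed-form distance on small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
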