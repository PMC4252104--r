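Package: pegasm
Title: Paired-End Guided Greedy De Novo Assembly of Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A paired-end guided greedy de novo assembler for short
    sequencing reads (50-150 bp). Contigs are grown base by base from a
    sampled k-mer index of the read set, with paired-end read pools
    consulted first and single-end reads swept over decreasing overlap
    thresholds; ambiguous branches are classified by a polynomial-kernel
    support vector machine over branch features and, at low confidence,
    resolved by a look-ahead comparison of candidate forward paths that
    separates sequencing-error bubbles from short tandem repeats.
    A second phase orders and orients contigs into scaffolds from a
    placement-weighted linking graph, estimates inter-contig gaps from
    insert sizes, merges overlapping neighbours and closes gaps by local
    assembly. Includes a paired-end read simulator with controllable
    tandem-repeat structure and an evaluation harness (N50, reference
    coverage, mis-assembly calls, branch-decision tallies).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    kernlab,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
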