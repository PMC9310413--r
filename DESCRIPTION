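Package: sgc
Title: Two-Order Reference-Based Compression of Genome Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lossless compression of collections of highly similar genome
    sequences in FASTA format against a shared reference genome. Each record
    is split into a pure-ACGT base stream and auxiliary streams (identifier,
    line layout, soft-masking, N runs, rare ambiguity symbols); base streams
    are greedily matched against a k-mer-indexed reference (first-order
    compression); the resulting token streams of later sequences are matched
    against those of the first S compressed sequences (second-order
    compression); everything is serialized with delta/varint coding into an
    indexed single-file archive with a block-sorting entropy-coding final
    stage. Archives support selective per-sequence decompression. Includes a
    deterministic synthetic-fixture generator (mutated genome collections
    with soft-masked, N-run and ambiguity decoration) and command-line entry
    points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
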