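Package: bqf
Title: Backpack Quotient Filter for k-mer Abundance Indexing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic, space-efficient index for DNA k-mers with abundance.
    Implements the backpack quotient filter: a rank-and-select quotient filter
    whose slots carry a small saturating counter next to each remainder,
    combined with the fimpera scheme (index s-mers, s <= k, and answer a k-mer
    query as the minimum abundance over its constituent s-mers). An invertible
    xorshift-multiply hash makes stored elements enumerable, so the table can
    be resized by doubling when the load factor exceeds 95%. Includes readers
    for counted k-mer text dumps and FASTA/FASTQ, a binary index serialization,
    a command-line interface, and synthetic-data evaluation utilities
    (construction false-positive rate, s-sweeps, bits-per-element bounds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
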