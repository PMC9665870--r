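Package: matchstat
Title: Matching Statistics Toolkit with Compact Bitvector Encodings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the matching statistics (MS) array between a query and a
    text with the two-phase Burrows-Wheeler backward-search algorithm, stores
    it in the 2|S|-bit unary-difference bitvector encoding, reproduces the
    result with a block-decomposed parallel scheme that is bit-identical to
    the sequential scan, compresses the encoding lossily under a user
    threshold by optimal window permutation (a dynamic program over run-pair
    DAGs, with D, DL and ND cost variants), and answers range-maximum,
    range-sum, reporting and window analytics queries over plain or
    run-length-compressed encodings. Includes a synthetic generator of
    mutated sequence pairs for controlled experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, Biostrings
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
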