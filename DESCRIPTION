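Package: phagesig
Title: Compositional Signature Scanning and Replication Origin Detection
    for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects compositionally anomalous, putatively horizontally
    acquired regions in small genomes by sliding-window tetranucleotide
    Z-score correlation against the whole-genome signature, and predicts
    the replication origin and terminus from the cumulative GC skew.
    Z-scores follow the maximal-order Markov model on
    reverse-complement-extended sequences. Includes a seeded Markov-chain
    genome simulator that builds chimeric genomes with known foreign
    inserts, so every analysis stage is testable against ground truth
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
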