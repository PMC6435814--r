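Package: curatedblast
Title: Candidate Gene Discovery by Homology to Experimentally
    Characterized Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds candidate genes for a capability in a microbial genome
    without relying on automated annotations. A free-text query (with
    optional '%' wildcards and whole-word matching) is matched against the
    curated descriptions of experimentally characterized proteins; the
    matching protein sequences are then aligned to the genome's predicted
    proteins and, for genomes under 30 Mb, to stop-free stretches of at
    least 30 amino acids from the six-frame translation of the nucleotide
    sequence. Hits are ranked by the product of percent identity and
    percent coverage of the characterized protein, and six-frame hits that
    are already explained by a predicted protein are suppressed by a
    redundancy filter, so that the remaining six-frame hits point at
    missed genes and frameshift errors in gene models. Includes a builder
    for the curated-protein database from normalized per-source tables, a
    deterministic built-in Smith-Waterman alignment engine, report writers
    (TSV, JSON, HTML), a command-line interface, and generators for
    synthetic genomes with planted genes used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
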