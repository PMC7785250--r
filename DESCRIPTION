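Package: piconflict
Title: Small-RNA Signatures and Evolutionary Tests for a piRNA-Mediated
    Transposon-Gene Conflict
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses for the genetic conflict between a telomeric
    retrotransposon that has captured a segment of a host gene and the host
    gene it consequently targets via the piRNA pathway. Implements piRNA
    ping-pong (10-nt 5' overlap) and Zucchini phasing (3'-to-5' distance of 1)
    signature statistics, degradome-seq cleavage-overlap detection with two
    permutation tests, allele-specific small-RNA base counting at diagnostic
    substitution sites, coverage-ratio transposon copy-number estimation with
    a 5'-UTR truncation mixture model, the Tajima relative rate test with
    substitution-timing classification against the captured sequence, and the
    genome-wide knockdown fold-change ranking procedure. A synthetic-data
    module generates every input with planted ground truth so the whole
    pipeline is exercisable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
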