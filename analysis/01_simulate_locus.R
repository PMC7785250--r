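#!/usr/bin/env Rscript
# Stage 1: build the synthetic conflict locus — a TE whose 3' UTR carries a
# captured gene segment (17 diagnostic substitutions), mirrored into the 5'
# UTR — and write its sequences, annotation, and planted truth.

suppressPackageStartupMessages(library(piconflict))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 3L
dir.create("results", showWarnings = FALSE)

locus <- make_conflict_locus(seed = seed)
print(locus)

write_fasta(c(locus$te_sequence, locus$gene_sequence), "results/locus.fa")
utils::write.table(locus$diagnostic_sites, "results/diagnostic_sites.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

truth <- list(
  seed = seed,
  te_length = nchar(locus$te_sequence),
  gene_length = nchar(locus$gene_sequence),
  captured_interval_gene = locus$captured_interval_gene,
  captured_interval_te3 = locus$captured_interval_te3,
  captured_interval_te5 = locus$captured_interval_te5,
  orf_intervals = locus$te_orf_intervals,
  n_diagnostic_sites = nrow(locus$diagnostic_sites),
  cleavage_positions = locus$cleavage_positions,
  n_te_copies = locus$n_te_copies,
  truncation_fraction = locus$truncation_fraction
)
jsonlite::write_json(truth, "results/locus_truth.json", auto_unbox = TRUE)

# sanity: mirrored coordinates of the diagnostic sites
m <- mirror_coordinate(locus$diagnostic_sites$te_pos,
                       locus$captured_interval_te3,
                       locus$captured_interval_te5[1])
stopifnot(identical(m, locus$diagnostic_sites$te_pos5))
cat("Wrote locus FASTA,", nrow(locus$diagnostic_sites),
    "diagnostic sites, and truth JSON to results/\n")
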