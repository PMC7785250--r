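#!/usr/bin/env Rscript
# Stage 3: simulate degradome fragments and gene-targeting antisense piRNAs,
# call 10-nt sense:antisense cleavage overlaps, and run both permutation
# tests (B = 1,000).

suppressPackageStartupMessages(library(piconflict))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 3L
dir.create("results", showWarnings = FALSE)

locus <- make_conflict_locus(seed = seed)
region <- locus$captured_interval_gene

degradome <- simulate_degradome(locus, mean_reads_per_site = 2, n_decoys = 7,
                                seed = derive_seed(seed, 31))
pirnas <- simulate_gene_pirnas(locus, mean_reads_per_site = 5,
                               n_background = 300,
                               seed = derive_seed(seed, 32))
write_alignment_table(degradome, "results/degradome_alignments.tsv")
write_alignment_table(pirnas, "results/gene_pirna_alignments.tsv")

calls <- call_overlaps(degradome, pirnas, region)
cat(sprintf("%d planted cleavage sites; %d distinct degradome 5' locations; %d with a 10-nt overlap\n",
            length(locus$cleavage_positions),
            length(unique(read_5p(degradome))), nrow(calls)))
utils::write.table(calls, "results/overlap_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pc <- pirna_5p_counts(pirnas, region)
abundance <- permutation_test_abundance(calls$position + 9L, pc, B = 1000L,
                                        seed = derive_seed(seed, 33))
n_locations <- length(unique(read_5p(degradome)))
overlap <- permutation_test_overlap_count(n_locations, nrow(calls), pc,
                                          region, B = 1000L,
                                          seed = derive_seed(seed, 34))
cat("Abundance test (are overlap locations piRNA-rich?):\n"); print(abundance)
cat("Overlap-count test (more 10-nt overlaps than chance?):\n"); print(overlap)

jsonlite::write_json(list(
  n_calls = nrow(calls),
  n_degradome_locations = n_locations,
  abundance_test = list(B = abundance$B, k = abundance$k, p = abundance$p),
  overlap_count_test = list(B = overlap$B, k = overlap$k, p = overlap$p)
), "results/degradome_tests.json", auto_unbox = TRUE, digits = NA)
cat("Wrote overlap calls and permutation results to results/\n")
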