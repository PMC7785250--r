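#!/usr/bin/env Rscript
# Stage 2: simulate a piRNA library from the TE, then measure the library's
# strand bias, ping-pong 10-nt overlap signature, phasing signature, and the
# allele-specific assignment of diagnostic bases.

suppressPackageStartupMessages(library(piconflict))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 3L
dir.create("results", showWarnings = FALSE)

locus <- make_conflict_locus(seed = seed)
reads <- simulate_small_rna(locus, n_reads = 20000,
                            pingpong_pair_fraction = 0.3,
                            phased_fraction = 0.3,
                            background_fraction = 0.4,
                            antisense_fraction = 0.59,
                            seed = derive_seed(seed, 2))
reads <- filter_pirna_lengths(reads)
write_alignment_table(reads, "results/pirna_alignments.tsv")

cat(sprintf("Library: %d reads after 23-30 nt filter; %.1f%% antisense\n",
            nrow(reads), 100 * mean(reads$strand == "-")))

cov <- stranded_coverage(reads, nchar(locus$te_sequence), normalize = "RPM",
                         library_total = nrow(reads))
utils::write.table(
  data.frame(position = seq_along(cov$plus) - 1L,
             plus_rpm = cov$plus, minus_rpm = cov$minus),
  "results/pirna_coverage_rpm.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

pp <- pingpong_signature(reads)
ph <- phasing_signature(reads)
print(pp); print(ph)
utils::write.table(
  data.frame(distance = pp$distances, pingpong_pairs = pp$counts),
  "results/pingpong_histogram.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
utils::write.table(
  data.frame(distance = ph$distances, phasing_pairs = ph$counts),
  "results/phasing_histogram.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

antisense <- reads[reads$strand == "-", ]
ac <- assign_alleles(antisense, locus$diagnostic_sites, frame = "te")
print(ac)

jsonlite::write_json(list(
  n_reads = nrow(reads),
  antisense_fraction = mean(reads$strand == "-"),
  pingpong_z10 = pp$z, pingpong_c10 = pp$counts[10],
  phasing_z1 = ph$z, phasing_c1 = ph$counts[1],
  alleles = list(n_te = ac$n_te, n_gene = ac$n_gene, n_other = ac$n_other,
                 total = ac$total, percent = as.list(ac$percent))
), "results/smallrna_signatures.json", auto_unbox = TRUE, digits = NA)
cat("Wrote signature histograms, RPM coverage, and summary JSON to results/\n")
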