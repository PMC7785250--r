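test_that("conflict locus plants the requested diagnostic structure", {
  tr <- default_locus()
  sites <- tr$diagnostic_sites
  expect_equal(nrow(sites), 17)
  expect_true(all(sites$gene_allele != sites$te_allele))

  # mirrored 5'-UTR copy is character-identical to the 3'-UTR copy
  te <- tr$te_sequence
  cap3 <- substr(te, tr$captured_interval_te3[1] + 1, tr$captured_interval_te3[2])
  cap5 <- substr(te, tr$captured_interval_te5[1] + 1, tr$captured_interval_te5[2])
  expect_identical(cap3, cap5)

  # captured intervals in all three frames have equal lengths
  widths <- c(diff(tr$captured_interval_gene), diff(tr$captured_interval_te3),
              diff(tr$captured_interval_te5))
  expect_equal(length(unique(widths)), 1L)

  # every site carries the planted alleles at the stated coordinates
  expect_equal(substring(te, sites$te_pos + 1, sites$te_pos + 1),
               sites$te_allele)
  expect_equal(substring(tr$gene_sequence, sites$gene_pos + 1,
                         sites$gene_pos + 1), sites$gene_allele)
  expect_true(all(sites$te_pos >= tr$captured_interval_te3[1] &
                    sites$te_pos < tr$captured_interval_te3[2]))
})

test_that("zero diagnostic sites give an identical captured segment", {
  tr <- make_conflict_locus(n_diagnostic_sites = 0L, seed = 5)
  cap_te <- substr(tr$te_sequence, tr$captured_interval_te3[1] + 1,
                   tr$captured_interval_te3[2])
  cap_gene <- substr(tr$gene_sequence, tr$captured_interval_gene[1] + 1,
                     tr$captured_interval_gene[2])
  expect_identical(unname(cap_te), unname(cap_gene))
})

test_that("generators are deterministic given a seed", {
  expect_identical(make_conflict_locus(seed = 11), make_conflict_locus(seed = 11))
  tr <- default_locus()
  expect_identical(simulate_small_rna(tr, n_reads = 200, seed = 2),
                   simulate_small_rna(tr, n_reads = 200, seed = 2))
  expect_identical(simulate_genomic_coverage(tr, seed = 2),
                   simulate_genomic_coverage(tr, seed = 2))
  expect_identical(simulate_counts(n_genes = 100, n_knockdowns = 2, seed = 2),
                   simulate_counts(n_genes = 100, n_knockdowns = 2, seed = 2))
  expect_identical(simulate_triplet(seed = 2), simulate_triplet(seed = 2))
})

test_that("infeasible generator parameters are rejected", {
  expect_error(make_conflict_locus(captured_length = 10L,
                                   n_diagnostic_sites = 17L), "diagnostic sites")
  tr <- default_locus()
  expect_error(simulate_small_rna(tr, pingpong_pair_fraction = 0.9,
                                  phased_fraction = 0.9,
                                  background_fraction = 0.9), "sum to 1")
  expect_error(simulate_small_rna(tr, length_range = c(10L, 30L)),
               "length_range")
})

test_that("simulated small-RNA libraries respect lengths and placement", {
  tr <- default_locus()
  reads <- simulate_small_rna(tr, n_reads = 600, seed = 4)
  len <- reads$end - reads$start
  expect_true(all(len >= 23 & len <= 30))
  expect_true(all(reads$start >= 0 & reads$end <= nchar(tr$te_sequence)))
  expect_equal(nchar(reads$sequence), len)
})

test_that("pure ping-pong libraries pair every sense read at overlap 10", {
  tr <- default_locus()
  reads <- simulate_small_rna(tr, n_reads = 200, pingpong_pair_fraction = 1,
                              phased_fraction = 0, background_fraction = 0,
                              seed = 6)
  truth <- attr(reads, "truth")
  expect_equal(truth$n_pingpong_pairs, 100)
  p5 <- read_5p(reads)
  plus5 <- p5[reads$strand == "+"]
  minus5 <- p5[reads$strand == "-"]
  expect_true(all((plus5 + 9L) %in% minus5))

  bg <- simulate_small_rna(tr, n_reads = 100, pingpong_pair_fraction = 0,
                           phased_fraction = 0, background_fraction = 1,
                           seed = 6)
  expect_equal(attr(bg, "truth")$n_pingpong_pairs, 0)
})

test_that("error-free reads from the TE haplotype carry the TE allele", {
  tr <- default_locus()
  reads <- simulate_small_rna(tr, n_reads = 400, pingpong_pair_fraction = 0,
                              phased_fraction = 0, background_fraction = 1,
                              error_rate = 0, seed = 8)
  ac <- assign_alleles(reads, tr$diagnostic_sites, frame = "te")
  expect_gt(ac$n_te, 0)
  expect_equal(ac$n_gene, 0)
  expect_equal(ac$n_other, 0)
})

test_that("degradome simulation places 5' ends at planted cleavage sites", {
  tr <- default_locus()
  dg <- simulate_degradome(tr, n_decoys = 0, seed = 2)
  expect_setequal(unique(read_5p(dg)), tr$cleavage_positions)
  expect_true(all(dg$strand == "+"))

  none <- make_conflict_locus(n_cleavage_sites = 0L, seed = 5)
  only_decoys <- simulate_degradome(none, n_decoys = 25, seed = 2)
  expect_equal(nrow(only_decoys), 25)
})

test_that("coverage simulation matches the mixture-model expectations", {
  tr0 <- make_conflict_locus(truncation_fraction = 0, seed = 5)
  cv <- simulate_genomic_coverage(tr0, depth = 50, seed = 7)
  orf_pos <- seq(tr0$te_orf_intervals$ORF1[1] + 1, tr0$te_orf_intervals$ORF2[2])
  expect_equal(mean(cv$track[orf_pos]) / cv$genome_median,
               tr0$n_te_copies, tolerance = 0.05)

  empty <- make_conflict_locus(n_te_copies = 0L, seed = 5)
  cv0 <- simulate_genomic_coverage(empty, depth = 50, seed = 7)
  expect_true(all(cv0$track == 0))

  tr1 <- make_conflict_locus(truncation_fraction = 1, seed = 5)
  cv1 <- simulate_genomic_coverage(tr1, depth = 80, seed = 7)
  cap <- seq(tr1$captured_interval_te3[1] + 1, tr1$captured_interval_te3[2])
  flank <- seq(tr1$te_flank3_interval[1] + 1, tr1$te_flank3_interval[2])
  expect_equal(mean(cv1$track[cap]) / mean(cv1$track[flank]), 0.5,
               tolerance = 0.05)
})

test_that("count simulation applies planted fold changes", {
  cs <- simulate_counts(n_genes = 2000, n_knockdowns = 6, seed = 3)
  fcres <- fold_changes(cs$control, cs$knockdowns)
  expect_equal(median(fcres$fc, na.rm = TRUE), 1, tolerance = 0.1)

  zero <- simulate_counts(n_genes = 50, n_knockdowns = 2, zero_genes = 5,
                          seed = 3)
  zg <- names(zero$truth$baseline)[zero$truth$baseline == 0]
  expect_true(all(zero$control[zg, ] == 0))
  expect_true(all(vapply(zero$knockdowns, function(m) all(m[zg, ] == 0), TRUE)))
})

test_that("triplet simulation realizes disjoint lineage-specific sites", {
  tri0 <- simulate_triplet(500, 0, 0, seed = 4)
  expect_equal(tri0$truth$m1, 0)
  expect_equal(length(unique(tri0$alignment)), 1L)

  # asymmetric rates put most substitutions on the fast branch
  more1 <- vapply(1:30, function(i) {
    tri <- simulate_triplet(2000, 0.02, 0.002, seed = derive_seed(40, i))
    tri$truth$m1 > tri$truth$m2
  }, TRUE)
  expect_gt(mean(more1), 0.9)
})
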