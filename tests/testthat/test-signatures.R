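test_that("length filter keeps exactly the piRNA range", {
  rd <- aligned_reads("r", c(0L, 0L, 0L, 0L), c(22L, 23L, 30L, 31L),
                      rep("+", 4))
  kept <- filter_pirna_lengths(rd)
  expect_equal(kept$end, c(23L, 30L))
  expect_equal(nrow(filter_pirna_lengths(rd[0, ])), 0)
  all_in <- aligned_reads("r", c(0L, 5L), c(25L, 31L), c("+", "-"))
  expect_equal(filter_pirna_lengths(all_in), all_in)
  expect_error(filter_pirna_lengths(rd, 30, 23), "min_len")
})

test_that("stranded coverage counts aligned bases per strand", {
  rd <- aligned_reads("r", 10L, 20L, "+")
  cov <- stranded_coverage(rd, 30L)
  expect_equal(cov$plus, c(rep(0, 10), rep(1, 10), rep(0, 10)))
  expect_equal(cov$minus, rep(0, 30))
  expect_equal(sum(cov$plus) + sum(cov$minus), sum(rd$end - rd$start))

  rpm <- stranded_coverage(rd, 30L, normalize = "RPM",
                           library_total = 2e6)
  expect_equal(rpm$plus, cov$plus / 2)
  expect_error(stranded_coverage(rd, 30L, normalize = "RPM"), "library_total")
  expect_error(stranded_coverage(rd, 15L), "beyond")
})

test_that("generator antisense bias is recovered in strand shares", {
  tr <- default_locus()
  reads <- simulate_small_rna(tr, n_reads = 10000, pingpong_pair_fraction = 0,
                              phased_fraction = 0, background_fraction = 1,
                              antisense_fraction = 0.59, seed = 12)
  expect_equal(mean(reads$strand == "-"), 0.59, tolerance = 0.05)
})

test_that("ping-pong overlap definition and histogram match the oracle", {
  # plus 5' at 100, minus 5' at 109 -> overlap 10
  rd <- aligned_reads("r", c(100L, 85L), c(126L, 110L), c("+", "-"))
  prof <- pingpong_signature(rd)
  expect_equal(prof$counts[10], 1)
  expect_equal(sum(prof$counts), 1)

  # exact agreement with O(n^2) enumeration on random inputs
  for (seed in c(21L, 22L, 23L)) {
    rd <- random_reads(300, seed = seed)
    prof <- pingpong_signature(rd)
    expect_equal(prof$counts, as.numeric(brute_pingpong_counts(rd)))
  }
})

test_that("phasing distance definition and histogram match the oracle", {
  rd <- aligned_reads("r", c(100L, 126L), c(126L, 152L), c("+", "+"))
  prof <- phasing_signature(rd)
  expect_equal(prof$counts[1], 1)

  # minus-strand head-to-tail adjacency in transcription direction
  rdm <- aligned_reads("r", c(100L, 74L), c(126L, 100L), c("-", "-"))
  expect_equal(phasing_signature(rdm)$counts[1], 1)

  for (seed in c(31L, 32L, 33L)) {
    rd <- random_reads(300, seed = seed)
    prof <- phasing_signature(rd)
    expect_equal(prof$counts, as.numeric(brute_phasing_counts(rd)))
  }
})

test_that("signatures are invariant under a global coordinate shift", {
  rd <- random_reads(200, seed = 41)
  shifted <- rd
  shifted$start <- rd$start + 1000L
  shifted$end <- rd$end + 1000L
  expect_equal(pingpong_signature(rd)$counts, pingpong_signature(shifted)$counts)
  expect_equal(phasing_signature(rd)$counts, phasing_signature(shifted)$counts)
})

test_that("degenerate backgrounds flag the z-score as undefined", {
  # a single pair: all background distances are zero -> sd 0 -> undefined
  rd <- aligned_reads("r", c(100L, 85L), c(126L, 110L), c("+", "-"))
  prof <- pingpong_signature(rd, max_overlap = 30L)
  expect_true(prof$z_undefined)
  expect_true(is.na(prof$z))
  # with background variation the z-score is defined and finite
  full <- random_reads(300, seed = 44)
  pf <- pingpong_signature(full)
  expect_false(pf$z_undefined)
  expect_true(is.finite(pf$z))
})

test_that("planted phased trails give a strong Z1", {
  tr <- default_locus()
  reads <- simulate_small_rna(tr, n_reads = 1000, pingpong_pair_fraction = 0,
                              phased_fraction = 0.8, background_fraction = 0.2,
                              seed = 14)
  expect_gt(phasing_signature(reads)$z, 3)
})

test_that("mean z10 does not decrease with the planted pair fraction", {
  tr <- default_locus()
  mean_z <- vapply(c(0.2, 0.5, 0.8), function(frac) {
    mean(vapply(1:5, function(i) {
      rd <- simulate_small_rna(tr, n_reads = 800,
                               pingpong_pair_fraction = frac,
                               phased_fraction = 0,
                               background_fraction = 1 - frac,
                               seed = derive_seed(50, i))
      pingpong_signature(rd)$z
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_z) > -0.5))
})
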