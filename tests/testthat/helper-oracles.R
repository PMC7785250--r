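# Independent brute-force oracles and small fixture builders, kept separate
# from the implementation paths they check.

# O(n^2) enumeration of ping-pong 5':5' overlap counts
brute_pingpong_counts <- function(reads, max_overlap = 30L) {
  counts <- integer(max_overlap)
  p5 <- read_5p(reads)
  plus <- which(reads$strand == "+")
  minus <- which(reads$strand == "-")
  for (i in plus) for (j in minus) {
    if (reads$ref[i] != reads$ref[j]) next
    d <- p5[j] - p5[i] + 1L
    if (d >= 1L && d <= max_overlap) counts[d] <- counts[d] + 1L
  }
  counts
}

# O(n^2) enumeration of same-strand 3'-to-5' distances (transcription
# direction; head-to-tail adjacency = 1)
brute_phasing_counts <- function(reads, max_distance = 51L) {
  counts <- integer(max_distance)
  p5 <- read_5p(reads)
  p3 <- read_3p(reads)
  n <- nrow(reads)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || reads$ref[i] != reads$ref[j] ||
        reads$strand[i] != reads$strand[j]) next
    d <- if (reads$strand[i] == "+") p5[j] - p3[i] else p3[i] - p5[j]
    if (d >= 1L && d <= max_distance) counts[d] <- counts[d] + 1L
  }
  counts
}

# a small uniform random read set on one reference
random_reads <- function(n, ref_length = 500L, seed = 1L,
                         len_range = c(20L, 30L)) {
  set.seed(seed)
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  start <- sample.int(ref_length - max(len_range), n, replace = TRUE) - 1L
  aligned_reads(ref = "r", start = start, end = start + len,
                strand = sample(c("+", "-"), n, replace = TRUE))
}

default_locus <- function(seed = 3L) make_conflict_locus(seed = seed)

full_reference_region <- function(truth) c(0L, nchar(truth$te_sequence))
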