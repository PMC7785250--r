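# Degradome cleavage-overlap detection and permutation tests.
#
# A slicer (Aub) cleavage guided by an antisense piRNA leaves a 5'
# monophosphate fragment whose 5' end overlaps the guide's 5' end by exactly
# 10 nt: if the fragment's plus-strand 5' end is at position d, the guide's
# minus-strand 5' end is at d + 9.

#' Tabulate piRNA 5'-end counts per position
#'
#' @param pirnas minus-strand piRNA alignment data frame.
#' @param region `c(start, end)` restriction (0-based half-open).
#' @return named integer vector: position -> number of piRNA 5' ends there.
#' @export
pirna_5p_counts <- function(pirnas, region) {
  p5 <- read_5p(pirnas)
  p5 <- p5[p5 >= region[1] & p5 < region[2]]
  tb <- table(p5)
  stats::setNames(as.integer(tb), names(tb))
}

#' Call 10-nt sense:antisense cleavage overlaps
#'
#' A call is made at plus-strand degradome 5' position `d` iff at least one
#' antisense piRNA has its 5' end at exactly `d + 9` (overlap length 10).
#'
#' @param degradome_reads plus-strand degradome alignment data frame.
#' @param antisense_pirnas minus-strand piRNA alignment data frame on the
#'   same transcript.
#' @param region `c(start, end)` restriction applied to both inputs.
#' @return data frame with `position`, `n_degradome`, `n_pirnas` (piRNA 5'
#'   ends at `position + 9`), one row per called position.
#' @export
call_overlaps <- function(degradome_reads, antisense_pirnas, region) {
  if (nrow(degradome_reads) && any(degradome_reads$strand != "+")) {
    stop("degradome reads must be plus-strand on the transcript")
  }
  if (nrow(antisense_pirnas) && any(antisense_pirnas$strand != "-")) {
    stop("piRNAs must be minus-strand (antisense) on the transcript")
  }
  d5 <- read_5p(degradome_reads)
  keep <- d5 >= region[1] & d5 < region[2]
  d5 <- d5[keep]
  pcount <- pirna_5p_counts(antisense_pirnas, region)
  if (length(d5) == 0L) {
    return(data.frame(position = integer(0), n_degradome = integer(0),
                      n_pirnas = integer(0)))
  }
  tb <- table(d5)
  pos <- as.integer(names(tb))
  n_pi <- pcount[as.character(pos + 9L)]
  n_pi[is.na(n_pi)] <- 0L
  hit <- n_pi >= 1L
  data.frame(position = pos[hit], n_degradome = as.integer(tb)[hit],
             n_pirnas = as.integer(n_pi)[hit])
}

permutation_result <- function(observed_statistic, B, k, seed,
                               paper_style = FALSE) {
  p <- if (paper_style) k / B else (k + 1) / (B + 1)
  structure(list(observed_statistic = observed_statistic, B = B, k = k,
                 p = p, seed = seed, paper_style = paper_style),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test: observed statistic =",
      paste(x$observed_statistic, collapse = ","),
      "\n  B =", x$B, ", k =", x$k, ", p =", format(x$p, digits = 3),
      if (x$paper_style) "(k/B)" else "((k+1)/(B+1))", "\n")
  invisible(x)
}

#' Permutation test: are overlap locations unusually piRNA-abundant?
#'
#' Each permutation samples `length(observed_positions)` distinct positions
#' from the set of positions carrying at least one piRNA 5' end and asks
#' whether the sampled per-position piRNA counts dominate the observed ones
#' — both vectors sorted in decreasing order and compared elementwise
#' (`statistic = "dominance"`), or compared by their totals
#' (`statistic = "sum"`).
#'
#' @param observed_positions positions of the called overlaps (each must
#'   carry >= 1 piRNA 5' end).
#' @param pirna_counts named vector from [pirna_5p_counts()].
#' @param B number of permutations.
#' @param seed integer seed.
#' @param statistic `"dominance"` (sorted elementwise >=) or `"sum"`.
#' @param paper_style if TRUE report `p = k/B` instead of the default
#'   `(k+1)/(B+1)`.
#' @return a `permutation_result`.
#' @export
permutation_test_abundance <- function(observed_positions, pirna_counts,
                                       B = 1000L, seed = 1L,
                                       statistic = c("dominance", "sum"),
                                       paper_style = FALSE) {
  statistic <- match.arg(statistic)
  m <- length(observed_positions)
  counts <- as.integer(pirna_counts)
  if (length(counts) < m) {
    stop("need at least ", m, " distinct piRNA positions, have ",
         length(counts))
  }
  obs <- pirna_counts[as.character(observed_positions)]
  if (any(is.na(obs) | obs < 1)) {
    stop("every observed position must carry >= 1 piRNA 5' end")
  }
  obs_sorted <- sort(as.integer(obs), decreasing = TRUE)
  obs_sum <- sum(obs)
  set.seed(seed)
  k <- 0L
  for (b in seq_len(B)) {
    samp <- counts[sample.int(length(counts), m)]
    hit <- if (statistic == "dominance") {
      all(sort(samp, decreasing = TRUE) >= obs_sorted)
    } else {
      sum(samp) >= obs_sum
    }
    if (hit) k <- k + 1L
  }
  permutation_result(obs_sorted, B, k, seed, paper_style)
}

#' Permutation test: are 10-nt overlaps more frequent than chance?
#'
#' Each permutation samples `n_observed_locations` distinct positions
#' uniformly from the region and counts how many have an antisense piRNA 5'
#' end exactly 9 nt downstream (i.e. would be called as a 10-nt overlap);
#' `k` counts permutations with at least `n_with_overlap` such positions.
#'
#' @param n_observed_locations number of distinct positions with >= 1
#'   degradome read.
#' @param n_with_overlap how many of those also showed the 10-nt overlap.
#' @param pirna_counts named vector from [pirna_5p_counts()].
#' @param region `c(start, end)` sampling universe.
#' @inheritParams permutation_test_abundance
#' @return a `permutation_result`.
#' @export
permutation_test_overlap_count <- function(n_observed_locations,
                                           n_with_overlap, pirna_counts,
                                           region, B = 1000L, seed = 1L,
                                           paper_style = FALSE) {
  if (n_with_overlap > n_observed_locations) {
    stop("n_with_overlap cannot exceed n_observed_locations")
  }
  width <- region[2] - region[1]
  if (width < n_observed_locations) {
    stop("region shorter than the number of sampled locations")
  }
  pirna_pos <- as.integer(names(pirna_counts))
  set.seed(seed)
  k <- 0L
  for (b in seq_len(B)) {
    samp <- region[1] + sample.int(width, n_observed_locations) - 1L
    stat <- sum((samp + 9L) %in% pirna_pos)
    if (stat >= n_with_overlap) k <- k + 1L
  }
  permutation_result(n_with_overlap, B, k, seed, paper_style)
}
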