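# Small-RNA signature statistics: length filtering, strand-aware coverage,
# the ping-pong 10-nt 5' overlap signature, and the Zucchini phasing
# (3'-to-5' distance of 1) signature.
#
# Both signatures summarize a distance histogram over read pairs with a
# z-score of the focal distance (10 for ping-pong, 1 for phasing) against
# the remaining distances as background.

#' Filter reads to the piRNA length range
#'
#' @param reads alignment data frame.
#' @param min_len,max_len inclusive length bounds (nt); defaults are the
#'   conventional piRNA range 23-30.
#' @return the subset of reads whose lengths fall in the range.
#' @export
filter_pirna_lengths <- function(reads, min_len = 23L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- reads$end - reads$start
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Strand-separated per-base coverage
#'
#' @param reads alignment data frame on a single reference.
#' @param ref_length reference length (nt).
#' @param normalize `"raw"` (each aligned base adds 1) or `"RPM"` (scaled by
#'   `1e6 / library_total`).
#' @param library_total total mapped reads in the library; required for RPM.
#' @return list of numeric vectors `plus` and `minus`, each of length
#'   `ref_length`.
#' @export
stranded_coverage <- function(reads, ref_length, normalize = c("raw", "RPM"),
                              library_total = NULL) {
  normalize <- match.arg(normalize)
  if (nrow(reads) && any(reads$end > ref_length)) {
    stop("read extends beyond the reference (length ", ref_length, ")")
  }
  one_strand <- function(sub) {
    cov <- numeric(ref_length)
    if (nrow(sub)) {
      # difference-array accumulation of interval coverage
      d <- numeric(ref_length + 1L)
      tb <- table(sub$start)
      d[as.integer(names(tb)) + 1L] <- d[as.integer(names(tb)) + 1L] +
        as.numeric(tb)
      te <- table(sub$end)
      d[as.integer(names(te)) + 1L] <- d[as.integer(names(te)) + 1L] -
        as.numeric(te)
      cov <- cumsum(d[seq_len(ref_length)])
    }
    cov
  }
  plus <- one_strand(reads[reads$strand == "+", , drop = FALSE])
  minus <- one_strand(reads[reads$strand == "-", , drop = FALSE])
  if (normalize == "RPM") {
    if (is.null(library_total) || library_total <= 0) {
      stop("RPM normalization needs library_total > 0")
    }
    scale <- 1e6 / library_total
    plus <- plus * scale
    minus <- minus * scale
  }
  list(plus = plus, minus = minus)
}

signature_profile <- function(kind, distances, counts, focal_distance) {
  bg <- counts[distances != focal_distance]
  z <- NA_real_
  undefined <- TRUE
  if (length(bg) >= 2L && stats::sd(bg) > 0) {
    z <- (counts[distances == focal_distance] - mean(bg)) / stats::sd(bg)
    undefined <- FALSE
  }
  structure(list(kind = kind, distances = distances, counts = counts,
                 focal_distance = focal_distance, z = z,
                 z_undefined = undefined),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  label <- if (x$kind == "pingpong") "Ping-pong 5' overlap" else
    "Phasing 3'-to-5' distance"
  cat(label, "signature\n")
  cat("  pairs at focal distance", x$focal_distance, ":",
      x$counts[x$distances == x$focal_distance], "\n")
  if (x$z_undefined) cat("  z: undefined (degenerate background)\n")
  else cat("  z:", format(x$z, digits = 4), "\n")
  invisible(x)
}

# counts, per offset k in `offsets`, of pairs (a, b) with pos_b = pos_a + k,
# from position multiplicity tables
cross_counts <- function(pos_a, pos_b, offsets) {
  if (!length(pos_a) || !length(pos_b)) {
    return(stats::setNames(numeric(length(offsets)), offsets))
  }
  ta <- table(pos_a)
  tb <- table(pos_b)
  va <- as.numeric(ta); pa <- as.integer(names(ta))
  vb <- as.numeric(tb); pb <- as.integer(names(tb))
  vapply(offsets, function(k) {
    idx <- match(pa + k, pb)
    sum(va * ifelse(is.na(idx), 0, vb[idx]))
  }, numeric(1))
}

#' Ping-pong 10-nt 5' overlap signature
#'
#' For every pair of a plus-strand and a minus-strand read on the same
#' reference, the 5':5' overlap is `d = (minus 5' end) - (plus 5' end) + 1`.
#' Pairs are counted per overlap length `1..max_overlap` and the signature
#' z-score compares the count at `d = 10` to the mean and standard deviation
#' of all other overlap lengths.
#'
#' @param reads alignment data frame (both strands).
#' @param max_overlap largest overlap length tabulated.
#' @return a `signature_profile` with `focal_distance = 10`.
#' @export
pingpong_signature <- function(reads, max_overlap = 30L) {
  distances <- seq_len(max_overlap)
  counts <- stats::setNames(numeric(max_overlap), distances)
  for (r in unique(reads$ref)) {
    sub <- reads[reads$ref == r, , drop = FALSE]
    p5 <- read_5p(sub)
    counts <- counts + cross_counts(p5[sub$strand == "+"],
                                    p5[sub$strand == "-"],
                                    distances - 1L)
  }
  signature_profile("pingpong", distances, unname(counts), 10L)
}

#' Phasing 3'-to-5' distance signature
#'
#' For ordered pairs of same-strand reads on the same reference, the
#' distance from the 3' end of one read to the 5' end of the next is
#' measured in the direction of transcription, so that immediate head-to-tail
#' adjacency gives distance 1. Distances are tabulated over
#' `1..max_distance` per strand and summed; the z-score compares the count
#' at distance 1 against distances `2..max_distance`.
#'
#' @param reads alignment data frame.
#' @param max_distance largest distance tabulated.
#' @return a `signature_profile` with `focal_distance = 1`.
#' @export
phasing_signature <- function(reads, max_distance = 51L) {
  distances <- seq_len(max_distance)
  counts <- stats::setNames(numeric(max_distance), distances)
  for (r in unique(reads$ref)) {
    sub <- reads[reads$ref == r, , drop = FALSE]
    for (s in c("+", "-")) {
      st <- sub[sub$strand == s, , drop = FALSE]
      if (nrow(st) < 2L) next
      p5 <- read_5p(st)
      p3 <- read_3p(st)
      # plus strand: next 5' = prev 3' + d; minus strand: next 5' = prev 3' - d
      off <- if (s == "+") distances else -distances
      counts <- counts + cross_counts(p3, p5, off)
    }
  }
  signature_profile("phasing", distances, unname(counts), 1L)
}
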