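# Coverage-ratio TE copy number and the 5'-UTR truncation mixture model.
#
# Copy number is the ratio of the median nonzero per-base depth over the TE
# coding sequence to the median depth over uniquely mappable genome
# positions. The truncation model explains reduced depth over the segment
# duplicated in both UTRs: with multireads split evenly between the two
# reference copies and a fraction f of copies lacking the 5' UTR, the
# expected depth of the duplicated segment relative to a 3'-UTR-only flank
# is (2 - f) / 2 — at most a 50% reduction (f = 1).

interval_positions <- function(intervals, track_length) {
  if (is.numeric(intervals) && !is.list(intervals)) intervals <- list(intervals)
  if (length(intervals) == 0L) stop("empty interval union")
  pos <- integer(0)
  for (iv in intervals) {
    if (iv[1] < 0 || iv[2] > track_length || iv[1] >= iv[2]) {
      stop("interval [", iv[1], ", ", iv[2], ") invalid for track of length ",
           track_length)
    }
    pos <- c(pos, seq(iv[1] + 1L, iv[2]))
  }
  unique(pos)
}

#' Median nonzero coverage over intervals
#'
#' @param track numeric per-base depth vector.
#' @param intervals a `c(start, end)` interval or list of them (0-based
#'   half-open); their union is used.
#' @return median of the positive depths over the union; 0 (with a warning)
#'   if no position has positive depth.
#' @export
median_nonzero_coverage <- function(track, intervals) {
  pos <- interval_positions(intervals, length(track))
  v <- track[pos]
  v <- v[v > 0]
  if (length(v) == 0L) {
    warning("no nonzero coverage in the requested intervals")
    return(0)
  }
  stats::median(v)
}

#' Coverage-ratio TE copy number
#'
#' @param te_track per-base depth over the TE reference.
#' @param orf_intervals interval(s) covering the TE coding sequence
#'   (ORF1 + ORF2).
#' @param genome_median median per-base depth over uniquely mappable genome
#'   positions (per haploid copy).
#' @return a `copy_number_result` list: `med_te`, `med_genome`, `C`.
#' @export
estimate_copy_number <- function(te_track, orf_intervals, genome_median) {
  if (genome_median <= 0) stop("genome_median must be > 0")
  med_te <- median_nonzero_coverage(te_track, orf_intervals)
  structure(list(med_te = med_te, med_genome = genome_median,
                 C = med_te / genome_median),
            class = "copy_number_result")
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat("TE copy number C =", format(x$C, digits = 4),
      "(median TE CDS depth", x$med_te, "/ genome median", x$med_genome, ")\n")
  invisible(x)
}

#' ORF-normalized regional coverage
#'
#' Mean depth over a region divided by the median nonzero depth over the
#' ORFs, controlling for copy number. With `window`, per-window means (in
#' consecutive windows of that many bases) are returned alongside the
#' overall ratio.
#'
#' @param te_track per-base depth over the TE reference.
#' @param region `c(start, end)` region of interest.
#' @param orf_intervals interval(s) covering the TE coding sequence.
#' @param window optional window size (nt) for per-window ratios.
#' @return the ratio, or (with `window`) a list of `ratio` and `windows`
#'   (data frame of window starts and ratios).
#' @export
region_relative_coverage <- function(te_track, region, orf_intervals,
                                     window = NULL) {
  orf_med <- median_nonzero_coverage(te_track, orf_intervals)
  if (orf_med <= 0) stop("zero ORF coverage; cannot normalize")
  pos <- seq(region[1] + 1L, region[2])
  ratio <- mean(te_track[pos]) / orf_med
  if (is.null(window)) return(ratio)
  starts <- seq(region[1], region[2] - 1L, by = window)
  wins <- vapply(starts, function(s) {
    e <- min(s + window, region[2])
    mean(te_track[seq(s + 1L, e)]) / orf_med
  }, numeric(1))
  list(ratio = ratio, windows = data.frame(start = starts, ratio = wins))
}

#' Expected relative coverage of the duplicated segment
#'
#' Under the mixture model — a fraction `f` of TE copies lack the 5' UTR and
#' multireads from the duplicated segment are split evenly between its two
#' reference copies — the expected depth of the duplicated segment relative
#' to a 3'-UTR-only flank is `(2 - f) / 2`.
#'
#' @param f truncation fraction in `[0, 1]`.
#' @return expected relative coverage.
#' @export
truncation_expected_ratio <- function(f) {
  if (any(f < 0 | f > 1)) stop("truncation fraction must be in [0, 1]")
  (2 - f) / 2
}

#' Truncation fraction from observed relative coverage
#'
#' Inverts [truncation_expected_ratio()]: `f = 2 (1 - r)`, clamped to
#' `[0, 1]` (with a warning when clamping is active).
#'
#' @param r observed duplicated-segment : flank coverage ratio (> 0).
#' @return a `truncation_result` list: `r`, `f`, `expected_r` (the model
#'   ratio at the clamped `f`).
#' @export
truncation_fraction_estimate <- function(r) {
  if (r <= 0) stop("relative coverage must be > 0")
  f_raw <- 2 * (1 - r)
  f <- min(max(f_raw, 0), 1)
  if (f != f_raw) {
    warning("estimated truncation fraction ", format(f_raw, digits = 3),
            " clamped to [0, 1]")
  }
  structure(list(r = r, f = f, expected_r = truncation_expected_ratio(f)),
            class = "truncation_result")
}

#' @export
print.truncation_result <- function(x, ...) {
  cat("Truncation mixture model: relative coverage r =",
      format(x$r, digits = 4), "-> f =", format(x$f, digits = 4), "\n")
  cat("  (expected r at this f:", format(x$expected_r, digits = 4),
      "; max reduction 50% at f = 1)\n")
  invisible(x)
}
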