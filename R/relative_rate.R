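# Tajima relative rate test and substitution-timing classification.
#
# From a three-taxon alignment (two ingroups plus an outgroup) the test
# counts lineage-specific substitutions on each ingroup branch, polarized
# by the outgroup, and compares the two counts with
# chi^2 = (m1 - m2)^2 / (m1 + m2) on 1 degree of freedom. Timing
# classification asks, for each ingroup-1-specific substitution, whether a
# TE copy captured from that lineage carries the derived or the ancestral
# allele — substitutions postdating the capture leave the TE matching the
# ancestral (ingroup-2) state.

#' Count lineage-specific substitutions in a three-taxon alignment
#'
#' Per ungapped, unambiguous column: `ingroup1 != ingroup2` with
#' `ingroup2 == outgroup` is an ingroup-1-specific substitution;
#' symmetric for ingroup 2. Columns with gaps, non-ACGT characters, three
#' distinct states, or outgroup-only differences are excluded and counted.
#'
#' @param ingroup1,ingroup2,outgroup aligned sequences of equal length.
#' @return list with `m1`, `m2`, 0-based column positions `sites1` and
#'   `sites2`, and `n_excluded`.
#' @export
lineage_specific_substitutions <- function(ingroup1, ingroup2, outgroup) {
  if (nchar(ingroup1) != nchar(ingroup2) ||
      nchar(ingroup1) != nchar(outgroup)) {
    stop("the three aligned sequences must have equal lengths")
  }
  a <- strsplit(toupper(ingroup1), "")[[1]]
  b <- strsplit(toupper(ingroup2), "")[[1]]
  o <- strsplit(toupper(outgroup), "")[[1]]
  plain <- c("A", "C", "G", "T")
  usable <- a %in% plain & b %in% plain & o %in% plain
  is1 <- usable & a != b & b == o
  is2 <- usable & a != b & a == o
  informative <- usable & (a == b | is1 | is2)  # a==b covers outgroup-only diffs
  list(m1 = sum(is1), m2 = sum(is2),
       sites1 = which(is1) - 1L, sites2 = which(is2) - 1L,
       n_excluded = sum(!informative))
}

#' Tajima relative rate chi-squared test
#'
#' @param m1,m2 lineage-specific substitution counts for the two ingroups.
#' @return a `rate_test_result` list: `m1`, `m2`, `chi2`
#'   (`(m1 - m2)^2 / (m1 + m2)`), `df = 1`, and the upper-tail `p`.
#' @export
tajima_chi2 <- function(m1, m2) {
  if (m1 + m2 <= 0) stop("relative rate test undefined for m1 + m2 = 0")
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(list(m1 = m1, m2 = m2, chi2 = chi2, df = 1L, p = p),
            class = "rate_test_result")
}

#' @export
print.rate_test_result <- function(x, ...) {
  cat("Tajima relative rate test: m1 =", x$m1, ", m2 =", x$m2, "\n")
  cat("  chi^2 =", format(x$chi2, digits = 4), "(1 df), p =",
      format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Classify substitution timing against a captured TE sequence
#'
#' For each ingroup-1-specific substitution site, the TE sequence (aligned
#' into the same column space) is compared to the two ingroup alleles: a TE
#' base equal to the ingroup-2 (ancestral-proxy) allele means the
#' substitution postdates the capture; equal to the derived ingroup-1 allele
#' means it predates the capture. Sites where the TE has a gap/ambiguity or
#' matches neither allele fall into `n_other`.
#'
#' @param sites1 0-based column positions of ingroup-1-specific
#'   substitutions (from [lineage_specific_substitutions()]).
#' @param ingroup1,ingroup2 aligned ingroup sequences.
#' @param te_aligned TE sequence aligned in the same column space.
#' @return list with `n_te_matches_ingroup2`, `n_te_matches_ingroup1`,
#'   `n_other`, and the per-site classification data frame.
#' @export
classify_substitution_timing <- function(sites1, ingroup1, ingroup2,
                                         te_aligned) {
  if (nchar(te_aligned) != nchar(ingroup1)) {
    stop("TE sequence must be aligned to the same column space")
  }
  a <- strsplit(toupper(ingroup1), "")[[1]]
  b <- strsplit(toupper(ingroup2), "")[[1]]
  te <- strsplit(toupper(te_aligned), "")[[1]]
  idx <- sites1 + 1L
  cls <- ifelse(!te[idx] %in% c("A", "C", "G", "T"), "other",
         ifelse(te[idx] == b[idx], "matches_ingroup2",
         ifelse(te[idx] == a[idx], "matches_ingroup1", "other")))
  list(n_te_matches_ingroup2 = sum(cls == "matches_ingroup2"),
       n_te_matches_ingroup1 = sum(cls == "matches_ingroup1"),
       n_other = sum(cls == "other"),
       sites = data.frame(position = sites1, ingroup1 = a[idx],
                          ingroup2 = b[idx], te = te[idx], class = cls,
                          stringsAsFactors = FALSE))
}
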