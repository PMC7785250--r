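# Diagnostic sites, coordinate mirroring between the two UTR copies,
# masking, and allele-specific assignment of small-RNA bases.
#
# A diagnostic site is an aligned position where the TE and the gene carry
# different nucleotides; reads covering such sites can be assigned to the
# TE-derived or gene-derived allele base by base.

#' Extract diagnostic sites from a pairwise TE/gene alignment
#'
#' One site is reported per alignment column where both sequences have an
#' unambiguous, ungapped base and the bases differ. Columns containing gaps,
#' `N`, or any IUPAC ambiguity code in either sequence yield no site.
#' Ungapped 0-based coordinates are tracked per sequence.
#'
#' @param te_aligned,gene_aligned gapped aligned sequences (equal length;
#'   `-` for gaps).
#' @return data frame with columns `te_pos`, `gene_pos`, `te_allele`,
#'   `gene_allele`.
#' @export
diagnostic_sites_from_alignment <- function(te_aligned, gene_aligned) {
  if (nchar(te_aligned) != nchar(gene_aligned)) {
    stop("aligned sequences must have equal (gapped) lengths")
  }
  te <- strsplit(toupper(te_aligned), "")[[1]]
  ge <- strsplit(toupper(gene_aligned), "")[[1]]
  plain <- c("A", "C", "G", "T")
  te_pos <- cumsum(te != "-") - 1L
  gene_pos <- cumsum(ge != "-") - 1L
  keep <- te %in% plain & ge %in% plain & te != ge
  data.frame(te_pos = te_pos[keep], gene_pos = gene_pos[keep],
             te_allele = te[keep], gene_allele = ge[keep],
             stringsAsFactors = FALSE)
}

#' Mirror a 3'-UTR coordinate into the 5'-UTR copy
#'
#' The TE 5' UTR is a verbatim copy of the captured segment of the 3' UTR;
#' this maps positions between the two reference copies.
#'
#' @param p 0-based position(s) inside the captured 3'-UTR interval.
#' @param captured_te3 `c(start, end)` of the captured segment in the 3' UTR.
#' @param utr5_offset 0-based start of the copy in the 5' UTR.
#' @return mirrored position(s) in the 5'-UTR copy.
#' @export
mirror_coordinate <- function(p, captured_te3, utr5_offset = 0L) {
  if (any(p < captured_te3[1] | p >= captured_te3[2])) {
    stop("position outside the captured 3'-UTR interval")
  }
  utr5_offset + (p - captured_te3[1])
}

#' Inverse of [mirror_coordinate()]
#'
#' @param p5 position(s) in the 5'-UTR copy.
#' @inheritParams mirror_coordinate
#' @return position(s) in the captured 3'-UTR interval.
#' @export
unmirror_coordinate <- function(p5, captured_te3, utr5_offset = 0L) {
  width <- captured_te3[2] - captured_te3[1]
  rel <- p5 - utr5_offset
  if (any(rel < 0 | rel >= width)) {
    stop("position outside the 5'-UTR copy")
  }
  captured_te3[1] + rel
}

#' Mask intervals of a sequence with N
#'
#' Overlapping intervals are masked once (union). Length is preserved.
#'
#' @param seq a nucleotide string.
#' @param intervals list of `c(start, end)` 0-based half-open intervals.
#' @return masked sequence string.
#' @export
mask_intervals <- function(seq, intervals) {
  L <- nchar(seq)
  if (length(intervals) == 0L) return(seq)
  mask <- logical(L)
  for (iv in intervals) {
    if (iv[1] < 0 || iv[2] > L || iv[1] > iv[2]) {
      stop("interval [", iv[1], ", ", iv[2], ") outside sequence of length ", L)
    }
    if (iv[2] > iv[1]) mask[seq(iv[1] + 1L, iv[2])] <- TRUE
  }
  chars <- strsplit(seq, "")[[1]]
  chars[mask] <- "N"
  paste(chars, collapse = "")
}

#' Assign small-RNA bases to TE vs gene alleles at diagnostic sites
#'
#' For every (read, site) incidence — a read covering k sites contributes k
#' bases — the read base at the site is classified as matching the TE
#' allele, the gene allele, or neither. Reads without sequences are skipped
#' and counted. Read sequences are expected in reference orientation (see
#' [read_alignment_table()]), so the base at reference position `p` of a
#' read is `sequence[p - start + 1]` on either strand.
#'
#' @param reads alignment data frame with a `sequence` column, aligned to
#'   the coordinate frame named by `frame`.
#' @param sites diagnostic-site data frame (`te_pos`, `gene_pos`,
#'   `te_allele`, `gene_allele`).
#' @param frame `"te"` or `"gene"`: which coordinate column of `sites`
#'   matches the reads' reference.
#' @return an `allele_counts` list: `n_te`, `n_gene`, `n_other`, `total`,
#'   `percent` (named, summing to 100 within rounding), and
#'   `n_reads_skipped`.
#' @export
assign_alleles <- function(reads, sites, frame = c("te", "gene")) {
  frame <- match.arg(frame)
  pos_col <- if (frame == "te") "te_pos" else "gene_pos"
  has_seq <- "sequence" %in% names(reads) &
    !is.na(reads$sequence) & nzchar(reads$sequence)
  skipped <- sum(!has_seq)
  if (skipped > 0L) {
    message(skipped, " read(s) without sequence skipped")
  }
  rd <- reads[has_seq, , drop = FALSE]
  n_te <- 0L; n_gene <- 0L; n_other <- 0L
  for (i in seq_len(nrow(sites))) {
    p <- sites[[pos_col]][i]
    cov <- which(rd$start <= p & rd$end > p)
    if (!length(cov)) next
    base <- substring(rd$sequence[cov], p - rd$start[cov] + 1L,
                      p - rd$start[cov] + 1L)
    n_te <- n_te + sum(base == sites$te_allele[i])
    n_gene <- n_gene + sum(base == sites$gene_allele[i])
    n_other <- n_other + sum(base != sites$te_allele[i] &
                               base != sites$gene_allele[i])
  }
  allele_counts(n_te, n_gene, n_other, n_reads_skipped = skipped)
}

#' Summarize allele-specific base counts
#'
#' @param n_te,n_gene,n_other counts of diagnostic bases matching the TE
#'   allele, the gene allele, or neither.
#' @param n_reads_skipped reads dropped for lacking sequence.
#' @return an `allele_counts` list with the total and percentages.
#' @export
allele_counts <- function(n_te, n_gene, n_other, n_reads_skipped = 0L) {
  total <- n_te + n_gene + n_other
  pct <- if (total > 0) 100 * c(te = n_te, gene = n_gene, other = n_other) /
    total else c(te = NA_real_, gene = NA_real_, other = NA_real_)
  structure(list(n_te = n_te, n_gene = n_gene, n_other = n_other,
                 total = total, percent = pct,
                 n_reads_skipped = n_reads_skipped),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("Allele-specific diagnostic bases (n = ", x$total, ")\n", sep = "")
  cat(sprintf("  TE allele:    %6d (%s%%)\n", x$n_te,
              format(round(x$percent["te"], 1))))
  cat(sprintf("  gene allele:  %6d (%s%%)\n", x$n_gene,
              format(round(x$percent["gene"], 2))))
  cat(sprintf("  other:        %6d (%s%%)\n", x$n_other,
              format(round(x$percent["other"], 2))))
  if (x$n_reads_skipped > 0)
    cat("  (", x$n_reads_skipped, "reads without sequence skipped )\n")
  invisible(x)
}
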