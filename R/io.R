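# Readers/writers for the plain-text formats the pipeline touches, plus the
# small shared coordinate conventions every module relies on.
#
# Conventions (used everywhere downstream):
#   * intervals are 0-based half-open [start, end)
#   * a plus-strand read has its 5' end at `start` and 3' end at `end - 1`
#   * a minus-strand read has its 5' end at `end - 1` and 3' end at `start`
#   * read sequences are stored in reference (plus-strand) orientation

#' 5' end positions of aligned reads
#'
#' @param reads an alignment data frame (see [read_alignment_table()]).
#' @return integer vector of 0-based 5'-end positions, one per read.
#' @export
read_5p <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' 3' end positions of aligned reads
#'
#' @inheritParams read_5p
#' @return integer vector of 0-based 3'-end positions, one per read.
#' @export
read_3p <- function(reads) {
  ifelse(reads$strand == "+", reads$end - 1L, reads$start)
}

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T`. Only
#' `{A,C,G,T,N}` are accepted after normalization.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the FASTA ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for FASTA record '", ids[which(empty)[1]], "' in ", path)
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN character in FASTA record '", ids[which(bad)[1]], "' in ", path)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

ALIGNMENT_COLS <- c("ref", "start", "end", "strand", "read_id", "sequence",
                    "n_mismatches")

#' Read an alignment table
#'
#' The alignment dialect is a headered TSV with columns `ref`, `start`,
#' `end`, `strand` and optionally `read_id`, `sequence`, `n_mismatches`.
#' Coordinates are 0-based half-open; `sequence`, when present, is in
#' reference (plus-strand) orientation. Rows are preserved in file order.
#'
#' @param path path to the TSV.
#' @return data frame with one row per read.
#' @export
read_alignment_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("ref", "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("alignment table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  validate_reads(df)
  df
}

#' Write an alignment table
#'
#' @param reads alignment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(reads, path) {
  keep <- intersect(ALIGNMENT_COLS, names(reads))
  utils::write.table(reads[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an alignment data frame
#'
#' Checks the invariants every downstream statistic relies on: positive-width
#' intervals, `+`/`-` strands, and (when sequences are present) sequence
#' length equal to interval length.
#'
#' @param reads alignment data frame.
#' @return `reads`, invisibly.
#' @export
validate_reads <- function(reads) {
  if (nrow(reads) == 0L) return(invisible(reads))
  bad <- which(!(reads$start >= 0L & reads$start < reads$end))
  if (length(bad)) {
    stop("alignment row ", bad[1], ": need 0 <= start < end (got start=",
         reads$start[bad[1]], ", end=", reads$end[bad[1]], ")")
  }
  bad <- which(!reads$strand %in% c("+", "-"))
  if (length(bad)) {
    stop("alignment row ", bad[1], ": unknown strand symbol '",
         reads$strand[bad[1]], "'")
  }
  if ("sequence" %in% names(reads)) {
    has <- !is.na(reads$sequence) & nzchar(reads$sequence)
    bad <- which(has & nchar(reads$sequence) != reads$end - reads$start)
    if (length(bad)) {
      stop("alignment row ", bad[1], ": sequence length ",
           nchar(reads$sequence[bad[1]]), " != interval length ",
           reads$end[bad[1]] - reads$start[bad[1]])
    }
  }
  invisible(reads)
}

#' Construct an alignment data frame
#'
#' Convenience constructor applying the table conventions and validation.
#'
#' @param ref reference ids.
#' @param start,end 0-based half-open interval bounds.
#' @param strand `"+"` or `"-"` per read.
#' @param read_id optional read identifiers.
#' @param sequence optional sequences in reference orientation.
#' @param n_mismatches optional mismatch counts.
#' @return validated alignment data frame.
#' @export
aligned_reads <- function(ref, start, end, strand, read_id = NULL,
                          sequence = NULL, n_mismatches = NULL) {
  df <- data.frame(ref = as.character(ref), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  if (!is.null(read_id)) df$read_id <- as.character(read_id)
  if (!is.null(sequence)) df$sequence <- as.character(sequence)
  if (!is.null(n_mismatches)) df$n_mismatches <- as.integer(n_mismatches)
  validate_reads(df)
  df
}

#' Read a gene-by-sample count matrix
#'
#' First column holds gene ids; remaining columns are samples. Counts must
#' be non-negative integers; duplicated gene ids are rejected.
#'
#' @param path path to the TSV.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stop("count matrix ", path, " needs >= 2 columns")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicate gene id '", dup[1], "' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      stop("invalid count '", m[bad[1], j], "' for gene '", genes[bad[1]],
           "', sample '", colnames(m)[j], "' in ", path)
    }
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  m
}

#' Write a count matrix
#'
#' @param m integer matrix with gene rownames.
#' @param path output path.
#' @param id_col name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over `{A,C,G,T,N}`.
#' @return reverse-complemented character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
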