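# Synthetic-data generators with planted ground truth.
#
# These emulate the statistical structure of the study system: a telomeric
# retrotransposon (TE) whose 3' UTR carries a captured segment of a host
# gene, mirrored verbatim into the TE 5' UTR during replication; piRNA
# libraries with ping-pong pairs and phased trails; degradome cleavage
# fragments; genomic read depth over a mixture of full-length and
# 5'-truncated TE copies; negative-binomial knockdown count matrices; and
# three-taxon alignments with lineage-specific substitution rates.
# Every generator is deterministic given its seed and returns the planted
# truth needed by downstream recovery tests.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base <- function(base) {
  vapply(base, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
}

#' Derive a stage-specific child seed from a root seed
#'
#' Keeps multi-stage simulations reproducible from one root integer while
#' giving each stage its own stream.
#'
#' @param seed root integer seed.
#' @param stage small integer stage index.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 1664525 * as.numeric(stage)) %% 2147483629)
}

#' Simulate a transposon/gene conflict locus
#'
#' Builds a gene transcript and a TE consensus whose 3' UTR contains a
#' captured copy of part of the gene, differing from it at exactly
#' `n_diagnostic_sites` planted substitutions, with the captured segment
#' mirrored character-identically into the TE 5' UTR. Layout of the TE:
#' `[captured 5' UTR | ORF1 | ORF2 | 3'-UTR-only flank | captured 3' UTR]`.
#'
#' @param captured_length length of the captured gene segment (nt).
#' @param orf_length total length of the two ORFs (nt).
#' @param flank_length length of the 3'-UTR-only flank upstream of the
#'   captured copy (nt); this region exists once per TE copy and anchors the
#'   truncation-model coverage comparison.
#' @param gene_length gene transcript length (nt).
#' @param gene_capture_start 0-based start of the captured segment on the gene.
#' @param n_diagnostic_sites number of planted TE-vs-gene substitutions
#'   inside the captured segment.
#' @param n_te_copies genomic TE copy number.
#' @param truncation_fraction probability that a TE copy lacks its 5' UTR.
#' @param n_cleavage_sites number of planted slicer cleavage positions on the
#'   gene transcript (inside the captured region).
#' @param seed integer seed.
#' @return a `conflict_locus` list: sequences, all intervals (0-based
#'   half-open, as `c(start, end)`), the diagnostic-site table (absolute
#'   coordinates in both frames plus the mirrored 5'-UTR coordinate), planted
#'   cleavage positions, copy-number and truncation parameters.
#' @export
make_conflict_locus <- function(captured_length = 700L,
                                orf_length = 1800L,
                                flank_length = 300L,
                                gene_length = 2500L,
                                gene_capture_start = 1500L,
                                n_diagnostic_sites = 17L,
                                n_te_copies = 4L,
                                truncation_fraction = 0.5,
                                n_cleavage_sites = 11L,
                                seed = 1L) {
  if (n_diagnostic_sites > captured_length) {
    stop("cannot plant ", n_diagnostic_sites, " diagnostic sites in a ",
         captured_length, " nt captured segment")
  }
  if (gene_capture_start + captured_length > gene_length) {
    stop("captured segment extends beyond the gene transcript")
  }
  set.seed(seed)
  gene <- random_seq(gene_length)
  captured_gene <- substr(gene, gene_capture_start + 1L,
                          gene_capture_start + captured_length)

  offsets <- if (n_diagnostic_sites > 0L) {
    sort(sample.int(captured_length, n_diagnostic_sites) - 1L)
  } else integer(0)
  gene_alleles <- if (length(offsets)) {
    substring(captured_gene, offsets + 1L, offsets + 1L)
  } else character(0)
  te_alleles <- mutate_base(gene_alleles)
  captured_te <- captured_gene
  for (i in seq_along(offsets)) {
    substr(captured_te, offsets[i] + 1L, offsets[i] + 1L) <- te_alleles[i]
  }

  orf <- random_seq(orf_length)
  flank <- random_seq(flank_length)
  te <- paste0(captured_te, orf, flank, captured_te)

  Lc <- captured_length
  orf_start <- Lc
  utr3_start <- Lc + orf_length
  cap3_start <- utr3_start + flank_length
  te_len <- cap3_start + Lc

  half <- orf_length %/% 2L
  sites <- data.frame(
    gene_pos = gene_capture_start + offsets,
    te_pos = cap3_start + offsets,
    te_pos5 = offsets,
    gene_allele = unname(gene_alleles),
    te_allele = unname(te_alleles),
    stringsAsFactors = FALSE
  )

  cleavage <- if (n_cleavage_sites > 0L) {
    # keep >= 15 nt from the segment edges so the paired piRNA fits
    sort(sample(seq(gene_capture_start + 15L,
                    gene_capture_start + Lc - 16L), n_cleavage_sites))
  } else integer(0)

  structure(list(
    te_sequence = stats::setNames(te, "TE"),
    gene_sequence = stats::setNames(gene, "gene"),
    te_orf_intervals = list(ORF1 = c(orf_start, orf_start + half),
                            ORF2 = c(orf_start + half, utr3_start)),
    te_utr5_interval = c(0L, Lc),
    te_utr3_interval = c(utr3_start, te_len),
    te_flank3_interval = c(utr3_start, cap3_start),
    captured_interval_gene = c(gene_capture_start, gene_capture_start + Lc),
    captured_interval_te3 = c(cap3_start, te_len),
    captured_interval_te5 = c(0L, Lc),
    diagnostic_sites = sites,
    cleavage_positions = as.integer(cleavage),
    n_te_copies = as.integer(n_te_copies),
    truncation_fraction = truncation_fraction,
    seed = as.integer(seed)
  ), class = "conflict_locus")
}

#' @export
print.conflict_locus <- function(x, ...) {
  cat("Conflict locus: TE", nchar(x$te_sequence), "nt, gene",
      nchar(x$gene_sequence), "nt\n")
  cat("  captured segment:", diff(x$captured_interval_gene), "nt,",
      nrow(x$diagnostic_sites), "diagnostic sites\n")
  cat("  TE copies:", x$n_te_copies, " truncation fraction:",
      x$truncation_fraction, "\n")
  invisible(x)
}

apply_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < error_rate)
    for (i in hit) {
      substr(s, i, i) <- mutate_base(substr(s, i, i))
    }
    s
  }, "", USE.NAMES = FALSE)
}

extract_read_seq <- function(haplotype, start, end) {
  substring(haplotype, start + 1L, end)
}

#' Simulate a small-RNA (piRNA) library with planted signatures
#'
#' Generates reads on one reference haplotype as a mixture of three
#' components: ping-pong pairs (a sense read and an antisense read whose 5'
#' ends overlap by exactly 10 nt), phased trails (same-strand head-to-tail
#' runs with a 3'-to-5' distance of 1), and uniform background. Read lengths
#' are uniform over `length_range`; sequences are copied from the haplotype
#' (in reference orientation) with per-base substitution errors.
#'
#' @param truth a `conflict_locus` from [make_conflict_locus()].
#' @param n_reads target library size.
#' @param pingpong_pair_fraction,phased_fraction,background_fraction mixture
#'   proportions; must sum to 1.
#' @param antisense_fraction probability that a background read or phased
#'   trail is on the minus strand.
#' @param length_range inclusive piRNA length bounds, within 18-35 nt.
#' @param error_rate per-base substitution probability.
#' @param trail_length reads per phased trail.
#' @param frame `"te"` to draw reads from the TE haplotype, `"gene"` for the
#'   gene transcript.
#' @param region optional `c(start, end)` restriction for read placement;
#'   defaults to the captured interval of the chosen frame.
#' @param seed integer seed.
#' @return alignment data frame with a `truth` attribute recording the
#'   planted pair, trail, and background counts.
#' @export
simulate_small_rna <- function(truth, n_reads = 2000L,
                               pingpong_pair_fraction = 0.3,
                               phased_fraction = 0.3,
                               background_fraction = 0.4,
                               antisense_fraction = 0.59,
                               length_range = c(23L, 30L),
                               error_rate = 0.002,
                               trail_length = 5L,
                               frame = c("te", "gene"),
                               region = NULL,
                               seed = 1L) {
  frame <- match.arg(frame)
  fr <- c(pingpong_pair_fraction, phased_fraction, background_fraction)
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
    stop("mixture fractions must be non-negative and sum to 1")
  }
  if (length_range[1] < 18L || length_range[2] > 35L ||
      length_range[1] > length_range[2]) {
    stop("length_range must be increasing and within [18, 35]")
  }
  hap <- if (frame == "te") truth$te_sequence else truth$gene_sequence
  ref <- names(hap)
  L <- nchar(hap)
  if (is.null(region)) {
    region <- if (frame == "te") truth$captured_interval_te3 else
      truth$captured_interval_gene
  }
  set.seed(seed)
  lens <- function(k) sample(seq(length_range[1], length_range[2]), k,
                             replace = TRUE)
  lo <- max(region[1], length_range[2])          # margin so reads fit
  hi <- min(region[2], L) - length_range[2] - 10L
  if (hi <= lo) stop("region too short for the configured read lengths")

  starts <- integer(0); ends <- integer(0); strands <- character(0)

  n_pairs <- floor(n_reads * pingpong_pair_fraction / 2)
  if (n_pairs > 0) {
    p5 <- sample(seq(lo, hi), n_pairs, replace = TRUE)
    l_plus <- lens(n_pairs); l_minus <- lens(n_pairs)
    starts <- c(starts, p5, p5 + 10L - l_minus)
    ends <- c(ends, p5 + l_plus, p5 + 10L)
    strands <- c(strands, rep("+", n_pairs), rep("-", n_pairs))
  }

  n_phased <- floor(n_reads * phased_fraction)
  n_trails <- ceiling(n_phased / trail_length)
  n_phased <- n_trails * trail_length
  if (n_trails > 0) {
    for (t in seq_len(n_trails)) {
      minus <- stats::runif(1) < antisense_fraction
      l <- lens(trail_length)
      if (!minus) {
        s0 <- sample(seq(lo, hi - sum(l)), 1L)
        st <- s0 + c(0L, cumsum(l[-trail_length]))
        starts <- c(starts, st); ends <- c(ends, st + l)
        strands <- c(strands, rep("+", trail_length))
      } else {
        e0 <- sample(seq(lo + sum(l), hi), 1L)
        en <- e0 - c(0L, cumsum(l[-trail_length]))
        starts <- c(starts, en - l); ends <- c(ends, en)
        strands <- c(strands, rep("-", trail_length))
      }
    }
  }

  n_bg <- max(0L, n_reads - 2L * n_pairs - n_phased)
  if (n_bg > 0) {
    p5 <- sample(seq(lo, hi), n_bg, replace = TRUE)
    l <- lens(n_bg)
    minus <- stats::runif(n_bg) < antisense_fraction
    starts <- c(starts, ifelse(minus, p5 - l + 1L, p5))
    ends <- c(ends, ifelse(minus, p5 + 1L, p5 + l))
    strands <- c(strands, ifelse(minus, "-", "+"))
  }

  seqs <- apply_errors(extract_read_seq(hap, starts, ends), error_rate)
  reads <- aligned_reads(ref = rep(ref, length(starts)), start = starts,
                         end = ends, strand = strands,
                         read_id = sprintf("sr%05d", seq_along(starts)),
                         sequence = seqs)
  attr(reads, "truth") <- list(n_pingpong_pairs = n_pairs,
                               n_phased = n_phased, n_trails = n_trails,
                               n_background = n_bg)
  reads
}

#' Simulate degradome-seq cleavage fragments
#'
#' Each planted cleavage position on the gene transcript receives at least
#' one plus-strand read whose 5' end is exactly that position (a slicer
#' cleavage fragment); decoy reads are placed uniformly in the region.
#'
#' @param truth a `conflict_locus`.
#' @param mean_reads_per_site mean extra supporting reads per cleavage site
#'   (Poisson; each site gets 1 + Poisson(mean) reads).
#' @param n_decoys uniform decoy reads.
#' @param read_length fragment length (nt), clipped at the transcript end.
#' @param region optional `c(start, end)`; defaults to the captured gene
#'   interval.
#' @param seed integer seed.
#' @return alignment data frame of plus-strand degradome reads, with a
#'   `truth` attribute holding the planted cleavage positions.
#' @export
simulate_degradome <- function(truth, mean_reads_per_site = 2,
                               n_decoys = 0L, read_length = 80L,
                               region = NULL, seed = 1L) {
  gene <- truth$gene_sequence
  L <- nchar(gene)
  if (is.null(region)) region <- truth$captured_interval_gene
  set.seed(seed)
  pos <- truth$cleavage_positions
  reps <- if (length(pos)) 1L + stats::rpois(length(pos), mean_reads_per_site)
          else integer(0)
  p5 <- rep(pos, reps)
  if (n_decoys > 0L) {
    p5 <- c(p5, sample(seq(region[1], region[2] - 1L), n_decoys,
                       replace = TRUE))
  }
  if (length(p5) == 0L) {
    return(structure(aligned_reads(character(0), integer(0), integer(0),
                                   character(0)),
                     truth = list(cleavage_positions = pos)))
  }
  ends <- pmin(p5 + read_length, L)
  reads <- aligned_reads(ref = rep(names(gene), length(p5)), start = p5,
                         end = ends, strand = rep("+", length(p5)),
                         read_id = sprintf("dg%05d", seq_along(p5)))
  attr(reads, "truth") <- list(cleavage_positions = pos)
  reads
}

#' Simulate antisense piRNAs targeting the gene transcript
#'
#' Plants minus-strand piRNAs on the gene whose 5' ends sit exactly 9 nt
#' downstream of each cleavage position (the geometry of a 10-nt
#' sense:antisense overlap with a cleavage fragment), plus uniform
#' minus-strand background piRNAs across the captured region.
#'
#' @param truth a `conflict_locus`.
#' @param mean_reads_per_site mean piRNA support per cleavage site
#'   (1 + Poisson(mean)).
#' @param n_background uniform background piRNAs.
#' @param length_range inclusive piRNA length bounds.
#' @param seed integer seed.
#' @return alignment data frame of minus-strand piRNA reads on the gene.
#' @export
simulate_gene_pirnas <- function(truth, mean_reads_per_site = 5,
                                 n_background = 200L,
                                 length_range = c(23L, 30L), seed = 1L) {
  gene <- truth$gene_sequence
  region <- truth$captured_interval_gene
  set.seed(seed)
  pos <- truth$cleavage_positions
  reps <- if (length(pos)) 1L + stats::rpois(length(pos), mean_reads_per_site)
          else integer(0)
  p5 <- rep(pos + 9L, reps)
  if (n_background > 0L) {
    lo <- region[1] + length_range[2]
    p5 <- c(p5, sample(seq(lo, region[2] - 1L), n_background, replace = TRUE))
  }
  l <- sample(seq(length_range[1], length_range[2]), length(p5),
              replace = TRUE)
  aligned_reads(ref = rep(names(gene), length(p5)), start = p5 - l + 1L,
                end = p5 + 1L, strand = rep("-", length(p5)),
                read_id = sprintf("gp%05d", seq_along(p5)))
}

#' Simulate genomic read depth over the TE reference
#'
#' Models a genome carrying `n_te_copies` TE insertions of which a
#' binomial(`n`, `truncation_fraction`) draw lack the 5' UTR entirely. Every
#' copy contributes sequencing depth over the ORFs and 3' UTR; only
#' full-length copies contribute over the 5' UTR. Reads originating from the
#' captured segment (present in both UTRs and identical between them) are
#' split evenly between its two reference locations. Per-position counts are
#' Poisson around these expectations.
#'
#' @param truth a `conflict_locus`.
#' @param depth per-haploid-copy mean depth.
#' @param background_positions number of background genome positions used to
#'   form the uniquely-mappable genome median.
#' @param seed integer seed.
#' @return list with `track` (per-base depth over the TE), `genome_median`,
#'   `n_full`, `n_truncated`, `realized_truncation_fraction`, and the planted
#'   `truncation_fraction`.
#' @export
simulate_genomic_coverage <- function(truth, depth = 30,
                                      background_positions = 20000L,
                                      seed = 1L) {
  set.seed(seed)
  n <- truth$n_te_copies
  f <- truth$truncation_fraction
  L <- nchar(truth$te_sequence)
  n_trunc <- if (n > 0L) stats::rbinom(1L, n, f) else 0L
  n_full <- n - n_trunc

  mu <- rep(n * depth, L)
  cap5 <- truth$captured_interval_te5
  cap3 <- truth$captured_interval_te3
  # captured-segment molecules: n (3' copies) + n_full (5' copies), reads
  # split 50/50 between the two identical reference locations
  cap_mu <- (n + n_full) * depth / 2
  mu[seq(cap5[1] + 1L, cap5[2])] <- cap_mu
  mu[seq(cap3[1] + 1L, cap3[2])] <- cap_mu

  track <- stats::rpois(L, mu)
  genome_median <- stats::median(stats::rpois(background_positions, depth))
  list(track = as.numeric(track),
       genome_median = genome_median,
       n_full = n_full, n_truncated = n_trunc,
       realized_truncation_fraction = if (n > 0L) n_trunc / n else NA_real_,
       truncation_fraction = f)
}

#' Simulate knockdown count matrices
#'
#' Negative-binomial gene counts for one control sample and `n_knockdowns`
#' knockdown samples, with per-sample library-size factors and planted
#' per-gene fold changes applied multiplicatively to the knockdown means.
#'
#' @param n_genes number of genes.
#' @param n_knockdowns number of knockdown experiments.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of baseline
#'   expression means.
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param size_factor_sdlog log-normal spread of per-sample library sizes.
#' @param planted_fold_changes named numeric vector (gene -> multiplier)
#'   applied in every knockdown; unnamed genes get multiplier 1.
#' @param zero_genes number of genes with zero baseline mean.
#' @param seed integer seed.
#' @return list with `control` (matrix, one column), `knockdowns` (list of
#'   one-column matrices), and `truth` (planted multipliers, baseline means,
#'   size factors).
#' @export
simulate_counts <- function(n_genes = 5000L, n_knockdowns = 16L,
                            baseline_meanlog = log(100), baseline_sdlog = 1.2,
                            nb_dispersion = 0.05, size_factor_sdlog = 0.15,
                            planted_fold_changes = numeric(0),
                            zero_genes = 0L, seed = 1L) {
  set.seed(seed)
  genes <- sprintf("gene%05d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  if (zero_genes > 0L) base[sample.int(n_genes, zero_genes)] <- 0
  fc <- stats::setNames(rep(1, n_genes), genes)
  if (length(planted_fold_changes)) {
    unknown <- setdiff(names(planted_fold_changes), genes)
    if (length(unknown)) stop("planted fold change for unknown gene: ",
                              unknown[1])
    fc[names(planted_fold_changes)] <- planted_fold_changes
  }
  size <- 1 / nb_dispersion
  sf <- c(1, stats::rlnorm(n_knockdowns, 0, size_factor_sdlog))
  draw <- function(mu) {
    counts <- integer(n_genes)
    pos <- mu > 0
    counts[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
    matrix(counts, ncol = 1L, dimnames = list(genes, NULL))
  }
  control <- draw(base * sf[1])
  colnames(control) <- "control"
  kds <- lapply(seq_len(n_knockdowns), function(k) {
    m <- draw(base * fc * sf[k + 1L])
    colnames(m) <- sprintf("kd%02d", k)
    m
  })
  list(control = control, knockdowns = kds,
       truth = list(fold_changes = fc, baseline = stats::setNames(base, genes),
                    size_factors = sf))
}

#' Simulate a three-taxon alignment with lineage-specific substitutions
#'
#' Starts from a random ancestor (also the outgroup sequence) and applies
#' Poisson(rate x length) substitutions independently on the two ingroup
#' branches, at disjoint sites, each to a different base. Optionally derives
#' a TE sequence captured from ingroup 1 partway through its substitution
#' history: substitutions that predate the capture are shared with the TE,
#' later ones are not.
#'
#' @param length alignment length (nt).
#' @param rate1,rate2 expected substitutions per site on ingroup branches 1
#'   and 2.
#' @param capture_fraction if non-NULL, fraction of ingroup-1 substitutions
#'   that predate the TE capture event.
#' @param seed integer seed.
#' @return list with `alignment` (named character vector `ingroup1`,
#'   `ingroup2`, `outgroup`), optional `te` sequence in the same column
#'   space, and `truth` (`m1`, `m2`, site positions, and for the capture
#'   model the pre-capture site set).
#' @export
simulate_triplet <- function(length = 2000L, rate1 = 0.02, rate2 = 0.02,
                             capture_fraction = NULL, seed = 1L) {
  set.seed(seed)
  anc <- random_seq(length)
  n1 <- stats::rpois(1L, rate1 * length)
  n2 <- stats::rpois(1L, rate2 * length)
  if (n1 + n2 > length) stop("substitution rates too high for this length")
  sites_all <- sample.int(length, n1 + n2)
  s1 <- sort(sites_all[seq_len(n1)])
  s2 <- sort(sites_all[n1 + seq_len(n2)])
  sub_at <- function(seqs, pos) {
    for (p in pos) substr(seqs, p, p) <- mutate_base(substr(seqs, p, p))
    seqs
  }
  ing1 <- sub_at(anc, s1)
  ing2 <- sub_at(anc, s2)
  te <- NULL; pre <- NULL
  if (!is.null(capture_fraction)) {
    n_pre <- round(capture_fraction * n1)
    pre <- sort(sample(s1, n_pre))   # substitutions that predate the capture
    te <- anc
    for (p in pre) substr(te, p, p) <- substr(ing1, p, p)
    te <- stats::setNames(te, "TE")
  }
  list(alignment = c(ingroup1 = ing1, ingroup2 = ing2, outgroup = anc),
       te = te,
       truth = list(m1 = n1, m2 = n2, sites1 = s1 - 1L, sites2 = s2 - 1L,
                    pre_capture_sites = if (is.null(pre)) NULL else pre - 1L))
}
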