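# Knockdown expression analysis: median-of-ratios normalization, fold
# changes against a control, the genome-wide "fold change >= focal gene in
# every knockdown" ranking, rank-sum group comparison, and Spearman
# correlation.

#' Median-of-ratios size-factor normalization
#'
#' For each sample j, the size factor is the median over genes (restricted
#' to genes with positive counts in every sample) of
#' `count_gj / geometric mean_g`; normalized counts are `count / s_j`.
#'
#' @param m counts matrix (genes x samples).
#' @return list with `normalized` (numeric matrix) and `size_factors`.
#' @export
median_of_ratios_normalize <- function(m) {
  m <- as.matrix(m)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) stop("no gene has positive counts in every sample")
  log_gm <- rowMeans(log(m[all_pos, , drop = FALSE]))
  sf <- apply(m[all_pos, , drop = FALSE], 2,
              function(col) stats::median(exp(log(col) - log_gm)))
  normalized <- sweep(m, 2, sf, "/")
  list(normalized = normalized, size_factors = sf)
}

#' Per-knockdown fold changes against a control
#'
#' Fold change for gene g in knockdown j is
#' `(normalized_kd + epsilon) / (normalized_control + epsilon)`. Genes with
#' zero control expression are flagged not-expressed and excluded. All
#' samples are normalized jointly by median-of-ratios before the ratio is
#' taken.
#'
#' @param control one-column counts matrix (genes x 1).
#' @param knockdowns list of one-column counts matrices over the same genes.
#' @param epsilon pseudocount added to both numerator and denominator.
#' @param exclude_targeted optional character vector, one gene id per
#'   knockdown; that gene's fold change is set `NA` in its own knockdown
#'   (self-targeted gene exclusion).
#' @return list with `fc` (genes x knockdowns matrix over expressed genes),
#'   `expressed` (gene ids with nonzero control counts), `epsilon`, and
#'   `size_factors`.
#' @export
fold_changes <- function(control, knockdowns, epsilon = 0.5,
                         exclude_targeted = NULL) {
  genes <- rownames(control)
  for (kd in knockdowns) {
    if (!identical(rownames(kd), genes)) {
      stop("control and knockdown matrices must share an identical gene set")
    }
  }
  if (!is.null(exclude_targeted) &&
      length(exclude_targeted) != length(knockdowns)) {
    stop("exclude_targeted needs one gene id per knockdown")
  }
  joint <- do.call(cbind, c(list(control), knockdowns))
  norm <- median_of_ratios_normalize(joint)
  nm <- norm$normalized
  ctrl <- nm[, 1]
  expressed <- genes[control[, 1] > 0]
  fc <- sapply(seq_along(knockdowns), function(j) {
    (nm[expressed, j + 1L] + epsilon) / (ctrl[expressed] + epsilon)
  })
  fc <- matrix(fc, nrow = length(expressed),
               dimnames = list(expressed,
                               vapply(knockdowns, colnames, "")))
  if (!is.null(exclude_targeted)) {
    for (j in seq_along(exclude_targeted)) {
      g <- exclude_targeted[j]
      if (!is.na(g) && g %in% expressed) fc[g, j] <- NA_real_
    }
  }
  list(fc = fc, expressed = expressed, epsilon = epsilon,
       size_factors = norm$size_factors)
}

#' Rank a focal gene by fold-change dominance across knockdowns
#'
#' Counts the genes (excluding the focal gene) whose fold change is greater
#' than or equal to the focal gene's in every knockdown, and expresses that
#' count as a fraction of all expressed genes.
#'
#' @param fc fold-change matrix (expressed genes x knockdowns), e.g.
#'   `fold_changes(...)$fc`. `NA` entries (excluded self-targets) are
#'   ignored for the gene carrying them.
#' @param focal_gene gene id; must be a row of `fc`.
#' @param include_focal if TRUE the focal gene itself is counted among the
#'   dominating genes.
#' @return a `rank_result` list: `focal_gene`, `n_expressed`,
#'   `n_dominating`, `percentile` (`n_dominating / n_expressed`).
#' @export
rank_across_knockdowns <- function(fc, focal_gene, include_focal = FALSE) {
  if (!focal_gene %in% rownames(fc)) {
    stop("focal gene '", focal_gene, "' is not among the expressed genes")
  }
  focal <- fc[focal_gene, ]
  ok <- !is.na(focal)
  dominates <- apply(fc[, ok, drop = FALSE], 1, function(g) {
    use <- !is.na(g)
    all(g[use] >= focal[ok][use])
  })
  n_dom <- sum(dominates) - (!include_focal) * dominates[focal_gene]
  structure(list(focal_gene = focal_gene, n_expressed = nrow(fc),
                 n_dominating = as.integer(n_dom),
                 percentile = as.numeric(n_dom) / nrow(fc)),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat("Fold-change dominance rank for", x$focal_gene, "\n")
  cat("  ", x$n_dominating, "of", x$n_expressed,
      "expressed genes dominate in every knockdown (top",
      sprintf("%.1f%%)", 100 * x$percentile), "\n")
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Exact when both groups have at most 8 observations and no ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with the rank-sum statistic `U` and two-sided `p`.
#' @export
compare_groups_ranksum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  exact <- length(x) <= 8 && length(y) <= 8 && !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Average ranks for ties. Returns `NA` with `undefined = TRUE` when either
#' vector is constant.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho` and `undefined`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors with at least 3 observations")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, undefined = TRUE))
  }
  list(rho = stats::cor(x, y, method = "spearman"), undefined = FALSE)
}
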