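---
title: "Models and methods behind piconflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind piconflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piconflict)
```

piconflict analyzes a genetic conflict in which a telomeric retrotransposon
(TE) carries, in its 3′ UTR, a captured segment of a host gene, mirrored
verbatim into its 5′ UTR by the element's replication mechanism. Antisense
piRNAs from the captured region can direct slicer cleavage of the host
gene's transcripts. This vignette documents the statistical models, the
coordinate and parameter conventions, the design choices that were
genuinely open, and what the synthetic-data tests do and do not establish.

## Coordinate conventions

All internal coordinates are 0-based half-open `[start, end)`; printed
reports are 1-based where noted. A plus-strand read's 5′ end is `start` and
its 3′ end is `end − 1`; a minus-strand read's 5′ end is `end − 1` and its
3′ end is `start`. Every distance statistic below reduces to arithmetic on
these ends, which is why the convention is fixed package-wide. Read
sequences in alignment tables are stored in reference (plus-strand)
orientation, so the base a read places at reference position `p` is always
`sequence[p − start + 1]`.

## Small-RNA signature statistics

**Ping-pong.** Reciprocal piRNA amplification produces sense/antisense
pairs whose 5′ ends overlap by exactly 10 nt. For every (plus, minus) read
pair on one reference, the overlap is `d = minus5′ − plus5′ + 1`; pair
counts `c_d` are tabulated for `d = 1..30` and scored as
`z10 = (c10 − mean(c_d, d ≠ 10)) / sd(c_d, d ≠ 10)`.

**Phasing.** Zucchini processing leaves same-strand reads head-to-tail. For
ordered same-strand pairs the distance from one read's 3′ end to the next
read's 5′ end is measured in the direction of transcription, so immediate
adjacency gives 1; counts over `1..51` are scored as
`Z1 = (c1 − mean(c_2..51)) / sd(c_2..51)`.

Three choices here were open and are worth recording:

- *Background windows.* `{1..30}\{10}` for ping-pong and `{2..51}` for
  phasing are the conventional windows; both are arguments
  (`max_overlap`, `max_distance`), not constants.
- *Pair counting.* All qualifying read pairs are counted, not unique 5′-end
  pairs; with amplified libraries this weights positions by read abundance,
  which is the more common convention. The histogram implementation is
  verified against an O(n²) pair enumeration oracle in the tests, so the
  two routes cannot drift apart silently.
- *Per-strand phasing.* Phased trails are strand-specific by mechanism, so
  distances are computed per strand and the histograms summed.

A subtlety that surfaced during calibration: if a "uniform" null library is
generated inside a short window, the distance histogram acquires an
edge-induced decay (fewer pairs can realize large distances), biasing `Z1`
upward by several tenths. This is a property of the simulation window, not
of the statistic; null calibrations therefore place uniform reads over the
full reference. Real libraries are not uniform, and the z-scores should be
read as enrichment scores, not calibrated p-values.

## Allele-specific assignment

Diagnostic sites are alignment columns where the TE and gene carry
different unambiguous bases (columns with gaps, `N`, or IUPAC codes yield
no site — the sites of interest are clean substitutions). Bases are counted
per (read, site) incidence: a read covering k sites contributes k bases.
This matches the convention in which the reported denominator is "bases
aligned to one of these positions", and makes the totals invariant under
read-order permutation. How to summarize reads that span several sites with
conflicting calls is not specified by the per-base convention; no
read-level vote is attempted.

## Degradome overlap detection and permutation tests

A slicer cleavage guided by an antisense piRNA leaves a fragment whose
plus-strand 5′ end at `d` pairs with the guide's 5′ end at `d + 9`
(a 10-nt 5′:5′ overlap). `call_overlaps()` reports exactly this geometry.

Two permutation tests assess significance, both with B = 1,000 by default:

1. *Abundance*: are the piRNA positions implicated in overlaps unusually
   abundant? Each permutation samples the same number of distinct positions
   from all positions with ≥ 1 piRNA 5′ end. Two statistics are offered:
   the default `"dominance"` compares the sampled and observed count
   vectors sorted in decreasing order, elementwise; `"sum"` compares
   totals. The dominance reading follows the source procedure ("same or
   more piRNAs at each location"); since it is a vector comparison rather
   than a scalar tail statistic, its p-values are *not* uniformly
   distributed under the null — conservative when counts are heavily tied,
   anti-conservative when counts take many values. The `"sum"` statistic is
   a proper scalar statistic and calibrates cleanly; tests assert
   near-uniformity (KS < 0.1) for it and only the rejection-rate band for
   dominance.
2. *Overlap count*: are there more 10-nt overlaps than chance? Each
   permutation samples the observed number of degradome locations uniformly
   from the region and counts how many would be called. The statistic is a
   small integer (≤ 18 in the emulated design), so its null p-values are
   valid but discrete: uniformity can only hold up to jumps of
   `P(statistic = mode) ≈ 0.2`.

Sampling is without replacement over distinct positions ("locations" are
sites, not reads). The default p-value is `(k + 1)/(B + 1)`, which cannot
be zero; `paper_style = TRUE` reports `k/B` for concordance with reports
that print 0.002-style values at B = 1,000. Mismatch-tolerant alignment of
piRNAs to the transcript is upstream of this module; it consumes
placements.

## Copy number and the truncation mixture model

Copy number is `C = median nonzero depth over the TE CDS / median depth
over uniquely mappable genome positions`. The genome-side median is an
input scalar: mappability tracks, GC correction, and depth downsampling are
data preparation, not part of the statistic. Nonzero filtering on the TE
side discards positions lost to deletions or mapping gaps.

The captured segment appears in both UTRs and the two copies are
character-identical, so a read from either copy maps ambiguously.
Apportioning such multireads evenly (50/50) between the two reference
copies is the symmetric default — a real probabilistic assigner would
apportion by estimated copy abundance, and the even split is exact only
when abundances are equal; the split weight is the one explicit modeling
assumption here. Under it, with truncation fraction `f` (the fraction of
copies missing the 5′ UTR entirely):

- ORF and 3′-UTR-flank depth per position: `n·depth`
- captured-segment depth per reference copy: `(n + n_full)·depth / 2`

giving the expected ratio `r = (2 − f)/2`, a maximum 50% reduction at
`f = 1`, inverted as `f̂ = clamp(2(1 − r), 0, 1)`. The round trip
`f → r → f̂` is exact on `[0, 1]` and tested over a grid.

The coverage generator draws the number of truncated copies as
`Binomial(n, f)` and records the *realized* fraction in its truth; with the
default four copies the realized fraction is the quantity the estimator can
recover (±0.05 at depth 30), while the planted probability differs from it
by sampling noise of order 0.2. Per-position noise is Poisson, the minimal
model for depth counts.

## Tajima relative rate test and capture timing

Lineage-specific substitutions are counted per clean alignment column:
`(x, y, y)` is ingroup-1-specific, `(x, x, y)` is an outgroup-only
difference (uninformative), three distinct states are unpolarizable;
gap/ambiguity columns are excluded rather than imputed, and the excluded
count is reported. The test statistic is `χ² = (m1 − m2)²/(m1 + m2)` with
an upper-tail χ²₁ p-value and no continuity correction — counts (13, 3)
give exactly 6.25 and p = 0.0124, and (37, 40) give 0.117 and p = 0.73.
Timing classification compares the TE base at each fast-lineage site to
the two ingroup alleles: matching the ingroup-2 (ancestral-proxy) allele
means the substitution postdates the capture.

The triplet generator applies `Poisson(rate × length)` substitutions per
ingroup branch at disjoint sites (each to a different base), so realized
counts are recovered exactly and the χ² approximation can be calibrated:
at equal rates of 0.02/site over 2,000 nt (≈ 40 events per branch) the
empirical type-I error at α = 0.05 is within 5% ± 2% over 500 seeds, and
power at rates (0.02, 0.002) exceeds 80%. Disjointness slightly understates
homoplasy relative to real sequences; at these rates the effect is
negligible and it is what makes exact truth recovery possible.

## Knockdown fold-change ranking

Counts are normalized by median-of-ratios: size factor
`s_j = median_g(count_gj / geometric mean_g)` over genes positive in every
sample. Fold changes use a pseudocount, `FC = (norm_kd + ε)/(norm_ctrl + ε)`
with `ε = 0.5` — zero handling is otherwise unspecified and ε = 0.5
preserves ordering among expressed genes while keeping FC finite.
"Expressed" means a nonzero control count. The ranking counts genes
(excluding the focal gene itself; `include_focal` flips the convention,
which is not pinned down by the procedure's description) whose fold change
is ≥ the focal gene's in every knockdown; the percentile divides by the
number of expressed genes. A flag excludes each knockdown's own targeted
gene. Group comparisons wrap the Wilcoxon rank-sum test (exact for small
untied groups) and rank correlations are Spearman with average ranks.

The count generator is negative binomial (dispersion 0.05, log-normal
baseline means, log-normal library-size factors), with planted per-gene
multipliers applied in every knockdown — uniform responders, unlike real
knockdowns where effects vary by experiment; the ranking's "dominates in
all k experiments" criterion is therefore easier on synthetic data than on
real data, and recovery tests should be read as correctness checks, not
sensitivity estimates.

## Synthetic locus defaults

The generated TE is 3.5 kb: a 700-nt captured segment (as the whole 5′
UTR), 1.8 kb of ORF, a 300-nt 3′-UTR-only flank, then the 3′-UTR copy of
the captured segment; the gene transcript is 2.5 kb with the captured
segment at 1500–2200. Defaults plant 17 diagnostic substitutions, 11
cleavage positions, 4 TE copies, truncation probability 0.5, piRNA lengths
23–30 nt, and a 59% antisense strand bias — the structural scale of the
real locus reduced roughly fourfold so the full suite runs in seconds.
Library sizes (10³–2×10⁴ reads), depth 30–50×, 5,000-gene count matrices,
2-kb triplets, and the replicate counts used in tests (50–500 seeds) were
chosen as the smallest sizes at which the statistics operate in their
intended regimes. Determinism is bit-for-bit given a seed;
`derive_seed(seed, stage)` gives stages their own reproducible streams.

What the synthetic data does *not* emulate: indels and structural variation
within the captured region, sequencing-quality and GC biases, multimapping
beyond the two UTR copies, piRNA abundance heterogeneity across positions
(real piRNA 5′-end counts are heavy-tailed), and inter-experiment
variability of knockdown effects. Passing tests establish that each
statistic computes what it claims and recovers planted parameters under its
own model assumptions — not that those assumptions hold in any particular
real library.
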