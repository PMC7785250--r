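test_that("median-of-ratios size factors match the closed form", {
  m <- matrix(c(2L, 8L, 4L, 16L), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  norm <- median_of_ratios_normalize(m)
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  expect_equal(norm$normalized[, 1], norm$normalized[, 2])

  # idempotence: size factors of a normalized matrix are all 1
  renorm <- median_of_ratios_normalize(norm$normalized)
  expect_equal(unname(renorm$size_factors), c(1, 1), tolerance = 1e-10)

  zero <- matrix(c(0L, 1L, 1L, 0L), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(median_of_ratios_normalize(zero), "positive counts")
})

test_that("planted library-size differences are recovered as size factors", {
  cs <- simulate_counts(n_genes = 3000, n_knockdowns = 1,
                        size_factor_sdlog = 0, seed = 23)
  doubled <- cs$knockdowns[[1]]
  doubled[] <- as.integer(round(doubled * 2))
  norm <- median_of_ratios_normalize(cbind(cs$control, doubled))
  expect_equal(unname(norm$size_factors[2] / norm$size_factors[1]), 2,
               tolerance = 0.1)
})

test_that("fold changes use the pseudocount and drop unexpressed genes", {
  ctrl <- matrix(c(10L, 0L, 5L), dimnames = list(c("a", "b", "c"), "control"))
  kd <- matrix(c(20L, 4L, 5L), dimnames = list(c("a", "b", "c"), "kd1"))
  # bypass normalization effects by normalizing a symmetric pair
  res <- fold_changes(ctrl, list(kd))
  expect_setequal(res$expressed, c("a", "c"))
  expect_false("b" %in% rownames(res$fc))

  # with unit size factors the ratio is (20 + .5) / (10 + .5)
  raw <- fold_changes(matrix(c(10L, 8L), dimnames = list(c("a", "z"), "c")),
                      list(matrix(c(20L, 8L), dimnames = list(c("a", "z"), "k"))))
  sf <- raw$size_factors
  expect_equal(unname(raw$fc["a", 1]),
               unname((20 / sf[2] + 0.5) / (10 / sf[1] + 0.5)),
               tolerance = 1e-10)

  bad <- matrix(1L, dimnames = list("other", "k"))
  expect_error(fold_changes(ctrl, list(bad)), "gene set")
})

test_that("dominance ranking counts genes beating the focal everywhere", {
  fc <- matrix(c(2, 3, 3,
                 2, 4, 1), nrow = 3,
               dimnames = list(c("focal", "g1", "g2"), c("e1", "e2")))
  rk <- rank_across_knockdowns(fc, "focal")
  expect_equal(rk$n_dominating, 1L)
  expect_equal(rk$percentile, 1 / 3)

  top <- matrix(c(9, 1, 1, 9, 1, 1), nrow = 3,
                dimnames = list(c("focal", "g1", "g2"), c("e1", "e2")))
  expect_equal(rank_across_knockdowns(top, "focal")$n_dominating, 0L)
  expect_equal(rank_across_knockdowns(top, "focal",
                                      include_focal = TRUE)$n_dominating, 1L)
  expect_error(rank_across_knockdowns(fc, "absent"), "not among")
})

test_that("ranking is invariant to gene order and per-experiment rescaling", {
  set.seed(9)
  fc <- matrix(rlnorm(300), ncol = 3,
               dimnames = list(sprintf("g%03d", 1:100), c("e1", "e2", "e3")))
  base <- rank_across_knockdowns(fc, "g050")
  perm <- rank_across_knockdowns(fc[sample.int(100), ], "g050")
  expect_equal(perm$n_dominating, base$n_dominating)
  scaled <- sweep(fc, 2, c(0.1, 7, 2.5), "*")
  expect_equal(rank_across_knockdowns(scaled, "g050")$n_dominating,
               base$n_dominating)
})

test_that("a planted responder lands at the top of the ranking", {
  focal <- "gene00042"
  cs <- simulate_counts(n_genes = 4000, n_knockdowns = 16,
                        planted_fold_changes = stats::setNames(4, focal),
                        seed = 27)
  res <- fold_changes(cs$control, cs$knockdowns)
  rk <- rank_across_knockdowns(res$fc, focal)
  expect_lt(rk$percentile, 0.02)
})

test_that("rank-sum comparison matches exact enumeration on small groups", {
  # brute force: all 20 assignments of {1..6} into two groups of 3
  pool <- 1:6
  obs_u <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- obs_u(c(1, 2, 3), c(4, 5, 6))
  combs <- utils::combn(6, 3)
  us <- apply(combs, 2, function(idx) obs_u(pool[idx], pool[-idx]))
  mean_u <- mean(us)
  p_exact <- mean(abs(us - mean_u) >= abs(u_obs - mean_u))
  res <- compare_groups_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, p_exact)
  expect_equal(res$p, 0.1)

  same <- compare_groups_ranksum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.99)

  set.seed(5)
  shifted <- compare_groups_ranksum(rnorm(100), rnorm(100, mean = 2))
  expect_lt(shifted$p, 1e-6)
  expect_error(compare_groups_ranksum(numeric(0), 1), "non-empty")
})

test_that("spearman handles monotone, reversed, tied, and constant input", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  expect_true(spearman(rep(1, 5), 1:5)$undefined)
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 1, 4, 4, 6)
  expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)))
  # rank-transform invariance
  set.seed(11)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(spearman(a, b)$rho, spearman(rank(a), rank(b))$rho)
})

test_that("a planted rank correlation is recovered", {
  set.seed(31)
  n <- 1000
  z <- rnorm(n)
  rho_target <- 0.9
  # gaussian copula: latent pearson r giving spearman rho_target
  r <- 2 * sin(pi / 6 * rho_target)
  y <- r * z + sqrt(1 - r^2) * rnorm(n)
  expect_equal(spearman(z, y)$rho, 0.9, tolerance = 0.035)
})
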