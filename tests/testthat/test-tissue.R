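# exact two-sided rank-sum P by enumeration of all group assignments
enum_ranksum <- function(ranks_a, ranks_b) {
  all_ranks <- c(ranks_a, ranks_b)
  n <- length(all_ranks)
  na <- length(ranks_a)
  combs <- utils::combn(n, na)
  sums <- colSums(matrix(all_ranks[combs], nrow = na))
  obs <- sum(ranks_a)
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

test_that("TPM gene sets use a strict threshold", {
  m <- matrix(c(10, 11, 0, 25), 2, 2,
              dimnames = list(c("G1", "G2"), c("liver", "brain")))
  sets <- tpm_gene_sets(m, 10)
  expect_equal(sets$liver, "G2")   # exactly 10 is excluded
  expect_equal(sets$brain, "G2")
  sets_all <- tpm_gene_sets(m + 1, 0.5)
  expect_setequal(sets_all$liver, c("G1", "G2"))
  expect_error(tpm_gene_sets(matrix(numeric(0), 0, 0)), "empty")
  expect_error(tpm_gene_sets(-m, 10), "nonnegative")
})

test_that("TPM gene sets match a per-cell loop oracle", {
  set.seed(12)
  m <- matrix(rlnorm(50 * 6, 1.5, 1.3), 50, 6,
              dimnames = list(sprintf("G%02d", 1:50), letters[1:6]))
  sets <- tpm_gene_sets(m, 10)
  for (j in seq_len(ncol(m))) {
    oracle <- character(0)
    for (i in seq_len(nrow(m))) {
      if (m[i, j] > 10) oracle <- c(oracle, rownames(m)[i])
    }
    expect_identical(sets[[colnames(m)[j]]], oracle)
  }
})

test_that("directional sort ranks enrichment first and depletion last", {
  res <- data.frame(tissue = c("A", "B", "C"),
                    or_ = c(1.2, 0.8, 1.1), p = c(0.01, 0.01, 0.5))
  sorted <- directional_sort(res)
  expect_equal(sorted$tissue, c("A", "C", "B"))
  expect_equal(sorted$rank, 1:3)
  # all enriched: plain ascending P
  all_en <- data.frame(tissue = c("X", "Y", "Z"), or_ = c(1.5, 1.2, 1.1),
                       p = c(0.5, 0.001, 0.2))
  expect_equal(directional_sort(all_en)$tissue, c("Y", "Z", "X"))
  # depleted block: largest depletion P first, most significant last
  dep <- data.frame(tissue = c("D1", "D2", "E1"), or_ = c(0.5, 0.9, 2),
                    p = c(0.001, 0.6, 0.3))
  expect_equal(directional_sort(dep)$tissue, c("E1", "D2", "D1"))
  # OR exactly 1 closes the enriched block
  mid <- data.frame(tissue = c("M", "E", "D"), or_ = c(1, 1.3, 0.7),
                    p = c(0.001, 0.9, 0.9))
  expect_equal(directional_sort(mid)$tissue, c("E", "M", "D"))
  # determinism: input order never matters; sorting twice changes nothing
  perm <- res[c(3, 1, 2), ]
  expect_equal(directional_sort(perm)$tissue, sorted$tissue)
  expect_equal(directional_sort(sorted)$tissue, sorted$tissue)
})

test_that("brain-vs-other rank contrast is exact for small groups", {
  ranked <- data.frame(tissue = sprintf("T%d", 1:6), rank = 1:6)
  p <- brain_vs_other(ranked, sprintf("T%d", 1:3))
  # brain holds ranks {1,2,3}: 2 of the 20 assignments are as extreme
  expect_equal(as.numeric(p), 0.1, tolerance = 1e-12)
  expect_equal(as.numeric(p), enum_ranksum(1:3, 4:6), tolerance = 1e-12)
  # interleaved ranks: no location shift
  p_null <- brain_vs_other(ranked, sprintf("T%d", c(1, 4, 5)))
  expect_gt(as.numeric(p_null), 0.5)
  expect_error(brain_vs_other(ranked, character(0)), "non-empty")
  expect_error(brain_vs_other(ranked, ranked$tissue), "non-empty")
})

test_that("exact rank-sum agrees with enumeration on random splits", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(4:8, 1)
    na <- sample(2:(n - 2), 1)
    ranked <- data.frame(tissue = sprintf("T%d", 1:n), rank = 1:n)
    brain <- sample(ranked$tissue, na)
    p <- brain_vs_other(ranked, brain)
    oracle <- enum_ranksum(ranked$rank[ranked$tissue %in% brain],
                           ranked$rank[!ranked$tissue %in% brain])
    expect_equal(as.numeric(p), oracle, tolerance = 1e-12)
  }
})

test_that("planted brain enrichment drives brain tissues to low ranks", {
  tissues <- c(sprintf("brain_%d", 1:4), sprintf("other_%d", 1:8))
  brain <- tissues[1:4]
  low_p <- 0
  for (seed in 1:8) {
    cfg <- small_config(n_cases = 150, n_controls = 450, planted_genes = 15,
                        or_planted = 3)
    pipe <- small_pipeline(seed = 400 + seed, config = cfg)
    truth <- pipe$sim$truth
    expr <- simulate_expression(
      pipe$cohort$genes$gene, tissues, brain_labels = brain,
      elevated_genes = truth$planted_genes, brain_bias = 3,
      seed = 400 + seed
    )
    sets <- tpm_gene_sets(expr, 10)
    res <- tissue_scan(pipe$cohort, sets,
                       exclude_genes = truth$known_genes)
    ranked <- directional_sort(res)
    p <- brain_vs_other(ranked, brain)
    if (p < 0.05) low_p <- low_p + 1
  }
  expect_gte(low_p, 5)
})

test_that("unbiased expression leaves brain ranks exchangeable", {
  tissues <- c(sprintf("brain_%d", 1:4), sprintf("other_%d", 1:8))
  expr <- simulate_expression(sprintf("G%03d", 1:200), tissues,
                              brain_labels = tissues[1:4],
                              elevated_genes = NULL, brain_bias = 0,
                              seed = 77)
  sets <- tpm_gene_sets(expr, 10)
  expect_length(sets, 12)
  # identical seeds reproduce the matrix exactly
  expr2 <- simulate_expression(sprintf("G%03d", 1:200), tissues,
                               brain_labels = tissues[1:4],
                               elevated_genes = NULL, brain_bias = 0,
                               seed = 77)
  expect_identical(expr, expr2)
})
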