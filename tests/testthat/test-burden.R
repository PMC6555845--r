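test_that("per-individual counts are additive and respect restrictions", {
  samples <- make_samples(c("S1", "S2", "S3"),
                          c("case", "control", "control"))
  v <- rbind(
    make_variant(pos = 1, gene = "GENE1", effect = "stop_gained",
                 impact = "HIGH", carriers = "S1:het"),
    make_variant(pos = 2, gene = "GENE2", effect = "stop_gained",
                 impact = "HIGH", carriers = "S1:het"),
    make_variant(pos = 3, gene = "GENE1", preds = rep("D", 7),
                 carriers = "S1:het"),
    make_variant(pos = 4, gene = "GENE1", preds = c(rep("D", 6), "T"),
                 carriers = "S2:het")
  )
  co <- urv_cohort(v, samples, make_genes(c("GENE1", "GENE2")))
  co <- classify_variants(partition_by_rarity(co))
  counts <- count_urvs(co, "durv")
  expect_equal(counts[["S1"]], 3L)  # 2 null + 1 CD missense
  expect_equal(counts[["S2"]], 0L)
  # gene-set restriction: null variants outside the set do not count
  counts_g2 <- count_urvs(co, "null", gene_set = "GENE2")
  expect_equal(unname(counts_g2[c("S1", "S2", "S3")]), c(1L, 0L, 0L))
  expect_warning(count_urvs(co, "fcdhs_synonymous"), "zero count")
})

test_that("counts match a per-variant brute-force recount", {
  pipe <- small_pipeline(seed = 9)
  co <- pipe$cohort
  counts <- count_urvs(co, "durv")
  v <- co$variants
  ct <- carrier_table(co)
  oracle <- setNames(integer(nrow(co$samples)), co$samples$id)
  for (i in seq_len(nrow(ct))) {
    vi <- ct$variant[i]
    if (v$rarity[vi] == "singleton" &&
        v$class[vi] %in% c("null", "cd_missense")) {
      oracle[ct$id[i]] <- oracle[ct$id[i]] + 1L
    }
  }
  expect_equal(as.integer(counts), unname(oracle[names(counts)]))
})

test_that("with a single binary count the fit reduces to the 2x2 log odds ratio", {
  ids <- sprintf("S%02d", 1:40)
  status <- rep(c("case", "control"), each = 20)
  samples <- make_samples(ids, status)
  counts <- setNames(c(rep(1L, 12), rep(0L, 8), rep(1L, 5), rep(0L, 15)),
                     ids)
  fit <- fit_burden(counts, samples, covariates = character(0))
  expect_equal(fit$beta, log((12 * 15) / (8 * 5)), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_gt(fit$p, 0)
})

test_that("intercept absorption: shifting every count leaves OR and P unchanged", {
  pipe <- small_pipeline(seed = 13)
  counts <- count_urvs(pipe$cohort, "durv")
  f1 <- fit_burden(counts, pipe$cohort)
  shifted <- counts + 5L
  attributes(shifted) <- attributes(counts)
  f2 <- fit_burden(shifted, pipe$cohort)
  expect_equal(f1$or_, f2$or_, tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-6)
})

test_that("complete separation triggers the deterministic pseudo-count fix", {
  ids <- sprintf("S%02d", 1:30)
  samples <- make_samples(ids, rep(c("case", "control"), c(10, 20)))
  counts <- setNames(c(rep(1L, 5), rep(0L, 25)), ids)  # carriers all cases
  fit <- fit_burden(counts, samples, covariates = character(0))
  expect_true(fit$separation_flag)
  expect_true(fit$p_is_upper_bound)
  expect_lte(fit$p, 1)
  # the fix adds one variant to the lexicographically first control
  manual <- counts
  manual["S11"] <- manual["S11"] + 1L
  direct <- fit_burden(manual, samples, covariates = character(0))
  expect_equal(fit$beta, direct$beta, tolerance = 1e-8)
  expect_false(direct$separation_flag)
  # without separation the data pass through unchanged
  mixed <- counts
  mixed["S25"] <- 2L
  f_mixed <- handle_separation(mixed, samples, covariates = character(0))
  expect_false(f_mixed$separation_flag)
  # all-case input cannot be rescued
  expect_error(fit_burden(counts[1:10], samples[1:10, ],
                          covariates = character(0)),
               "at least one case and one control")
})

test_that("multiple-testing adjustment matches the printed family arithmetic", {
  # the family of 66 hypotheses: raw 0.000215 -> Bonferroni 0.0142
  expect_equal(signif(adjust_pvalues(0.000215, "bonferroni", m = 66), 3),
               0.0142)
  # hand application of the Benjamini-Hochberg step-up rule
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(0.7, "bonferroni", m = 1), 0.7)
  expect_error(adjust_pvalues(c(0.5, 0), "bh"), "\\(0, 1\\]")
  expect_error(adjust_pvalues(1.2, "bonferroni"), "\\(0, 1\\]")
})

test_that("bonferroni dominates BH dominates raw P, against naive oracles", {
  naive_bonferroni <- function(p, m) pmin(1, m * p)
  naive_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(1, adj)
    out
  }
  set.seed(101)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))^2
    bon <- adjust_pvalues(p, "bonferroni")
    bh <- adjust_pvalues(p, "bh")
    expect_equal(bon, naive_bonferroni(p, length(p)), tolerance = 1e-12)
    expect_equal(bh, naive_bh(p), tolerance = 1e-12)
    expect_true(all(bon >= bh - 1e-12 & bh >= p - 1e-12))
  }
})

test_that("a manifest of tests runs with family-wide adjustment", {
  pipe <- small_pipeline(seed = 21)
  known <- pipe$sim$truth$known_genes
  man <- burden_manifest(
    classes = c("durv", "other_synonymous"),
    gene_sets = list(all = NULL, known = known),
    subsets = list(all_cases = NULL)
  )
  res <- run_burden_tests(pipe$cohort, man)
  expect_equal(nrow(res), 4)
  expect_true(all(res$p_bonferroni >= res$p - 1e-12))
  expect_true(all(res$p_bh <= res$p_bonferroni + 1e-12))
  expect_true(all(res$or_ > 0))
})
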