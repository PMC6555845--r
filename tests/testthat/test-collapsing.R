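# independent oracle: full enumeration of the conditional 2x2 distribution
# from binomial coefficients, two-sided by the probability-mass rule
enum_fisher <- function(a, b, c_, d) {
  m <- a + b; nn <- c_ + d; k <- a + c_
  x <- max(0, k - nn):min(k, m)
  dens <- choose(m, x) * choose(nn, k - x) / choose(m + nn, k)
  d_obs <- dens[x == a]
  sum(dens[dens <= d_obs * (1 + 1e-7)])
}

test_that("two-tailed Fisher P follows the probability-mass rule", {
  # (3,0;0,3): the two extreme tables each carry mass 1/20
  expect_equal(fisher_two_tailed(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisher_two_tailed(1, 1, 1, 1), 1, tolerance = 1e-12)
  expect_equal(fisher_two_tailed(0, 0, 0, 0), 1)
  expect_error(fisher_two_tailed(-1, 0, 0, 1), "nonnegative")
})

test_that("Fisher P equals enumeration and fisher.test on random small tables", {
  set.seed(7)
  for (i in 1:300) {
    cells <- as.integer(rmultinom(1, sample(4:30, 1), runif(4)))
    got <- fisher_two_tailed(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, enum_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got, min(1, ft), tolerance = 1e-9)
  }
})

test_that("the gene scan counts carriers and flags significance bands", {
  samples <- make_samples(sprintf("S%02d", 1:30),
                          rep(c("case", "control"), c(10, 20)))
  nullv <- function(pos, gene, carriers) {
    make_variant(pos = pos, gene = gene, effect = "stop_gained",
                 impact = "HIGH", carriers = carriers)
  }
  v <- rbind(
    nullv(1, "GENE1", "S01:het"), nullv(2, "GENE1", "S02:het"),
    nullv(3, "GENE1", "S03:het"), nullv(4, "GENE1", "S02:het"),
    nullv(5, "GENE2", "S15:het"),
    nullv(6, "GENE3", "S05:het")
  )
  co <- urv_cohort(v, samples, make_genes(paste0("GENE", 1:3)))
  co <- classify_variants(partition_by_rarity(co))
  scan <- gene_burden_scan(co)
  g1 <- scan[scan$gene == "GENE1", ]
  expect_equal(g1$case_carriers, 3L)  # S02 carries two variants, counted once
  expect_equal(g1$control_carriers, 0L)
  expect_equal(g1$p, fisher_two_tailed(3, 7, 0, 20), tolerance = 1e-12)
  # zero-cell odds ratio uses 0.5 continuity on every cell
  expect_equal(g1$or_, (3.5 * 20.5) / (7.5 * 0.5), tolerance = 1e-12)
  # excluded genes and subset restriction
  expect_false("GENE2" %in% gene_burden_scan(co, exclude_genes = "GENE2")$gene)
  scan_sub <- gene_burden_scan(co, cases = c("S01", "S02"))
  expect_equal(scan_sub$n_case[1], 2L)
  # a gene carried only by individuals outside the subset is dropped
  scan_no5 <- gene_burden_scan(co, cases = sprintf("S%02d", c(1:4, 6:10)))
  expect_false("GENE3" %in% scan_no5$gene)
})

test_that("a strong case-only gene reaches exome-wide significance", {
  # 15 of 743 case carriers vs 0 of 2366 controls
  p <- fisher_two_tailed(15, 743 - 15, 0, 2366)
  expect_lt(p, 2.5e-6)
})

test_that("the planted high-odds-ratio gene is recovered among top hits", {
  hits <- 0
  for (seed in 1:10) {
    pipe <- small_pipeline(seed = 100 + seed,
                           config = small_config(planted_genes = 1,
                                                 or_planted = 30))
    planted <- pipe$sim$truth$planted_genes
    scan <- gene_burden_scan(pipe$cohort,
                             exclude_genes = pipe$sim$truth$known_genes)
    if (planted %in% utils::head(scan$gene, 5)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("label-shuffling overlap test is reproducible and bounded", {
  pipe <- small_pipeline(seed = 31)
  co <- pipe$cohort
  all_genes <- unique(co$variants$gene)
  r1 <- overlap_permutation(co, reference_set = all_genes, iterations = 60,
                            seed = 5)
  r2 <- overlap_permutation(co, reference_set = all_genes, iterations = 60,
                            seed = 5)
  expect_identical(r1$null_fractions, r2$null_fractions)
  expect_identical(r1$empirical_p, r2$empirical_p)
  # reference covering every gene: any nominal set overlaps fully
  if (r1$n_nominal > 0) {
    expect_equal(r1$observed_overlap_fraction, 1)
    expect_equal(r1$empirical_p, 1)
  }
  expect_length(r1$null_fractions, 60)
  expect_true(all(r1$null_fractions >= 0 & r1$null_fractions <= 1))
  expect_warning(
    overlap_permutation(co, reference_set = "NOT_A_GENE", iterations = 5,
                        seed = 1),
    "disjoint"
  )
  expect_error(overlap_permutation(co, reference_set = character(0)),
               "non-empty")
})

test_that("permutation empirical P uses the plain fraction with < 1/n reporting", {
  pipe <- small_pipeline(seed = 33,
                         config = small_config(planted_genes = 2,
                                               or_planted = 30))
  planted <- pipe$sim$truth$planted_genes
  res <- overlap_permutation(pipe$cohort, reference_set = planted,
                             iterations = 40, seed = 9,
                             exclude_genes = pipe$sim$truth$known_genes)
  expect_equal(res$empirical_p,
               mean(res$null_fractions >= res$observed_overlap_fraction))
  if (res$empirical_p == 0) expect_match(res$p_label, "^< ")
})
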