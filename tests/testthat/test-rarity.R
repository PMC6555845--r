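test_that("zygosity qualification follows the five per-chromosome rules", {
  # rule 1: heterozygous autosomal calls qualify regardless of sex
  expect_true(qualify_genotype("autosome", "het", "male"))
  expect_true(qualify_genotype("autosome", "het", "female"))
  expect_false(qualify_genotype("autosome", "hom", "male"))
  # rule 2: PAR behaves like an autosome
  expect_true(qualify_genotype("PAR", "het", "male"))
  expect_false(qualify_genotype("PAR", "hom", "female"))
  # rule 3: X-nonPAR het only for females and Klinefelter individuals
  expect_false(qualify_genotype("X_nonPAR", "het", "male"))
  expect_true(qualify_genotype("X_nonPAR", "het", "female"))
  expect_true(qualify_genotype("X_nonPAR", "het", "male", "XXY"))
  # rule 4: X-nonPAR hom = hemizygous, 46,XY males only
  expect_true(qualify_genotype("X_nonPAR", "hom", "male"))
  expect_true(qualify_genotype("X_nonPAR", "hemi", "male"))
  expect_false(qualify_genotype("X_nonPAR", "hom", "female"))
  expect_false(qualify_genotype("X_nonPAR", "hom", "male", "XXY"))
  # rule 5: Y hom for males, XXY included
  expect_true(qualify_genotype("Y", "hom", "male"))
  expect_true(qualify_genotype("Y", "hom", "male", "XXY"))
  expect_false(qualify_genotype("Y", "hom", "female"))
  expect_false(qualify_genotype("Y", "het", "male"))
  expect_error(qualify_genotype("mitochondrion", "het", "male"),
               "unknown site class")
})

test_that("rarity partition excludes panel variants and bins by allele count", {
  samples <- make_samples(sprintf("S%d", 1:6),
                          c("case", "case", rep("control", 4)))
  v <- rbind(
    make_variant(pos = 1, in_exac = 1, carriers = "S1:het"),
    make_variant(pos = 2, carriers = "S1:het,S2:het"),
    make_variant(pos = 3, carriers = "S3:het"),
    make_variant(pos = 4, in_tommo = 1, carriers = "S4:het,S5:het"),
    make_variant(pos = 5, carriers = "S1:het,S2:het,S3:het"),
    make_variant(pos = 6, carriers = "S1:het,S2:het,S3:het,S4:het"),
    make_variant(pos = 7, in_esp = 1, carriers = "S6:het"),
    make_variant(pos = 8, carriers = "S2:hom"),
    make_variant(chrom = "X", pos = 5e6, carriers = "S1:het"),
    make_variant(pos = 10, carriers = "S6:het")
  )
  co <- urv_cohort(v, samples, make_genes("GENE1"))
  co <- partition_by_rarity(co)
  r <- as.character(co$variants$rarity)
  # hand enumeration: S1 is male (alternating sex starts male), so the
  # X-nonPAR het call does not qualify (count 0); the autosomal hom call of
  # S2 fails rule 1 likewise -> both common_or_excluded
  expect_equal(r, c("common_or_excluded", "doubleton", "singleton",
                    "common_or_excluded", "tripleton", "common_or_excluded",
                    "common_or_excluded", "common_or_excluded",
                    "common_or_excluded", "singleton"))
  rep_ <- attr(co, "rarity_report")
  expect_equal(rep_$n_db_excluded, 3)
  # bins are disjoint and, with exclusions, cover the input
  expect_equal(sum(rep_$bins), nrow(co$variants))
})

test_that("an extra exclusion list removes variants like an external panel", {
  samples <- make_samples(c("S1", "S2"), c("case", "control"))
  v <- rbind(make_variant(pos = 100, ref = "A", alt = "T"),
             make_variant(pos = 200, ref = "G", alt = "C"))
  co <- urv_cohort(v, samples, make_genes("GENE1"))
  co <- partition_by_rarity(co, extra_exclude = "chr1:100:A:T")
  expect_equal(as.character(co$variants$rarity),
               c("common_or_excluded", "singleton"))
  rep_ <- attr(co, "rarity_report")
  expect_equal(rep_$n_extra_excluded, 1)
  expect_equal(rep_$fraction_extra_excluded, 0.5)
})

test_that("Grubbs exclusion removes gross outliers but spares tight clusters", {
  expect_equal(grubbs_outliers(c(50, 51, 52, 53, 54)), integer(0))
  x <- c(50, 51, 52, 53, 500)
  got <- grubbs_outliers(x, alpha = 0.001)
  expect_equal(got, 5L)
  # independent check of the decision: critical value from the
  # t distribution at alpha / (2N)
  n <- length(x)
  g <- max(abs(x - mean(x))) / sd(x)
  tcrit <- qt(0.001 / (2 * n), df = n - 2, lower.tail = FALSE)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  expect_true(g > gcrit)
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
})

test_that("Grubbs exclusions are rare on clean normal counts", {
  # familywise false-positive rate is ~alpha per dataset, so exclusions
  # across seeds should be close to zero
  total <- 0
  for (seed in 1:30) {
    set.seed(seed)
    total <- total + length(grubbs_outliers(rnorm(3000, 54.4, 8.2),
                                            alpha = 0.001))
  }
  expect_lte(total, 2)
})

test_that("count outlier exclusion is phenotype-blind and flags the planted outlier", {
  pipe <- small_pipeline(seed = 3)
  co <- pipe$cohort
  # plant one individual with a grossly inflated singleton count by giving
  # them many extra private variants
  target <- co$samples$id[1]
  extra <- do.call(rbind, lapply(1:400, function(i) {
    make_variant(pos = 9e6 + i, gene = co$genes$gene[1],
                 carriers = paste0(target, ":het"))
  }))
  v2 <- rbind(co$variants[, names(extra)], extra)
  co2 <- urv_cohort(v2, co$samples[, !names(co$samples) %in% "excluded"],
                    co$genes)
  co2 <- partition_by_rarity(co2)
  co2 <- classify_variants(co2)
  co2 <- exclude_count_outliers(co2)
  expect_true(target %in% attr(co2, "qc_report")$excluded_ids)
  # flipping phenotype labels changes nothing about the exclusion
  flipped <- co2$samples
  flipped$status <- ifelse(flipped$status == "case", "control", "case")
  co3 <- co2
  co3$samples <- flipped
  co3 <- exclude_count_outliers(co3)
  expect_equal(attr(co3, "qc_report")$excluded_ids,
               attr(co2, "qc_report")$excluded_ids)
})
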