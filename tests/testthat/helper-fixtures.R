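# In-code fixture builders shared across the suite.

# minimal sample manifest with covariate columns
make_samples <- function(ids, status, sex = NULL, karyotype = "normal",
                         callable = 0.96, seed_pcs = 0) {
  n <- length(ids)
  if (is.null(sex)) sex <- rep(c("male", "female"), length.out = n)
  pcs <- matrix(0, n, 10, dimnames = list(NULL, paste0("pc", 1:10)))
  if (seed_pcs > 0) {
    set.seed(seed_pcs)
    pcs[] <- rnorm(n * 10)
  }
  data.frame(id = ids, status = rep_len(status, n), sex = rep_len(sex, n),
             karyotype = rep_len(karyotype, n),
             callable_fraction = rep_len(callable, n), pcs,
             stringsAsFactors = FALSE)
}

# one variant-table row; prediction flags default NA
make_variant <- function(chrom = "1", pos = 1000, ref = "A", alt = "T",
                         gene = "GENE1", effect = "missense_variant",
                         impact = "MODERATE", preds = rep(NA_character_, 7),
                         splice_region = 0, in_exac = 0, in_esp = 0,
                         in_tommo = 0, carriers = "S1:het") {
  preds <- rep_len(preds, 7)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gene = gene,
             effect = effect, impact = impact,
             sift = preds[1], pph2_var = preds[2], pph2_div = preds[3],
             lrt = preds[4], mutation_taster = preds[5],
             mutation_assessor = preds[6], provean = preds[7],
             splice_region = splice_region, in_exac = in_exac,
             in_esp = in_esp, in_tommo = in_tommo, carriers = carriers,
             stringsAsFactors = FALSE)
}

make_genes <- function(gene_ids, pli = 0.5, mu = 1e-6) {
  data.frame(gene = gene_ids, pli = rep_len(pli, length(gene_ids)),
             mu_nonsense = mu, mu_frameshift = mu, mu_splice = mu,
             mu_missense = 10 * mu, mu_synonymous = 4 * mu,
             stringsAsFactors = FALSE)
}

# hand cohort: two variants, three samples
tiny_cohort <- function() {
  variants <- rbind(
    make_variant(pos = 100, gene = "GENE1", effect = "stop_gained",
                 impact = "HIGH", carriers = "S1:het"),
    make_variant(pos = 200, gene = "GENE2", preds = rep("D", 7),
                 carriers = "S2:het")
  )
  samples <- make_samples(c("S1", "S2", "S3"),
                          c("case", "control", "control"))
  urv_cohort(variants, samples, make_genes(c("GENE1", "GENE2")))
}

# small, fast simulation settings used throughout the suite
small_config <- function(...) {
  defaults <- list(n_cases = 80, n_controls = 240, n_genes = 150,
                   known_set_size = 8, x_gene_fraction = 0,
                   doubleton_fraction = 0.05, tripleton_fraction = 0.02,
                   db_present_rate = 0.05)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# simulate + partition + classify in one step
small_pipeline <- function(seed = 1, config = small_config(), dhs = TRUE) {
  sim <- simulate_cohort(config, seed = seed)
  co <- partition_by_rarity(sim$cohort)
  co <- classify_variants(co, dhs = if (dhs) sim$dhs else NULL)
  list(cohort = co, sim = sim)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
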