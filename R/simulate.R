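# Printed cohort-wide class tallies that the generator's default mixture
# emulates (coding URVs: null / Moderate / synonymous; Moderate split into
# consensus-damaging and other; synonymous split into DHS / splice-region /
# other; noncoding relative to coding).
.class_tallies <- list(
  null = 12032, moderate = 109063, synonymous = 47919, coding = 169014,
  cd_missense = 12337, other_moderate = 96726,
  fcdhs_synonymous = 11247, sr_synonymous = 1277, other_synonymous = 35608,
  noncoding = 42974
)

.default_class_props <- local({
  t <- .class_tallies
  syn_total <- t$fcdhs_synonymous + t$sr_synonymous + t$other_synonymous
  syn <- t$synonymous / t$coding
  c(null = t$null / t$coding,
    cd_missense = t$moderate / t$coding * (t$cd_missense / t$moderate),
    other_moderate = t$moderate / t$coding * (t$other_moderate / t$moderate),
    fcdhs_synonymous = syn * t$fcdhs_synonymous / syn_total,
    sr_synonymous = syn * t$sr_synonymous / syn_total,
    other_synonymous = syn * t$other_synonymous / syn_total)
})

#' Simulation configuration
#'
#' Defaults reproduce the study conditions the pipeline is designed for: a
#' cohort of 743 cases and 2366 controls with approximately normal
#' per-individual coding URV counts (mean 54.4, SD 8.2; slight
#' overdispersion relative to Poisson supplied by a per-individual gamma
#' multiplier), the printed functional-class mixture, small per-URV odds
#' ratios for damaging classes outside the known-disease genes, and a
#' 58-gene known set with a large per-URV odds ratio.
#'
#' @param n_cases,n_controls target group sizes; case status is drawn from
#'   a logistic liability whose intercept is solved so the expected case
#'   fraction is `n_cases / (n_cases + n_controls)`.
#' @param mean_urv_count,sd_urv_count marginal mean and SD of per-individual
#'   coding URV counts.
#' @param class_props named proportions of the six coding leaf classes
#'   (must sum to 1).
#' @param noncoding_mean mean per-individual noncoding URV count.
#' @param or_durv per-URV odds ratio of damaging URVs (null + consensus-
#'   damaging missense) in non-known genes.
#' @param or_known_durv per-URV odds ratio of damaging URVs in the known
#'   gene set.
#' @param or_fcdhs,or_sr per-URV odds ratios of the likely-functional
#'   synonymous subclasses.
#' @param n_genes,known_set_size number of genes and size of the known set.
#' @param x_gene_fraction fraction of genes placed on chromosome X.
#' @param gene_weight_sdlog log-SD of the lognormal gene length/weight
#'   distribution governing how variants distribute over genes.
#' @param planted_genes,or_planted number of extra high-odds-ratio genes
#'   planted outside the known set (picked among the heaviest autosomal
#'   genes so they accrue carriers) and their per-URV odds ratio.
#' @param doubleton_fraction,tripleton_fraction fractions of autosomal
#'   coding variants promoted to allele count 2 / 3 by adding carriers.
#' @param db_present_rate rate of additional variants flagged as present in
#'   the external panels (removed again by rarity filtering), relative to
#'   `mean_urv_count`.
#' @param xxy_rate probability that a male is 47,XXY.
#' @param callable_mean,callable_sd Beta-distributed proportion of callable
#'   loci.
#' @param mu_total named haploid genome-wide totals of the per-consequence
#'   de novo mutation rates, split over genes proportionally to weight.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 743, n_controls = 2366,
                       mean_urv_count = 54.4, sd_urv_count = 8.2,
                       class_props = .default_class_props,
                       noncoding_mean = 54.4 * 42974 / 169014,
                       or_durv = 1.07, or_known_durv = 10,
                       or_fcdhs = 1.05, or_sr = 1.05,
                       n_genes = 18396, known_set_size = 58,
                       x_gene_fraction = 0.02, gene_weight_sdlog = 0.75,
                       planted_genes = 0, or_planted = 6,
                       doubleton_fraction = 0.03, tripleton_fraction = 0.01,
                       db_present_rate = 0.05, xxy_rate = 0.001,
                       callable_mean = 0.9677, callable_sd = 0.0074,
                       mu_total = c(nonsense = 0.03, frameshift = 0.02,
                                    splice = 0.012, missense = 0.35,
                                    synonymous = 0.15)) {
  if (abs(sum(class_props) - 1) > 1e-9) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (any(c(or_durv, or_known_durv, or_fcdhs, or_sr, or_planted) <= 0)) {
    stop("odds ratios must be positive", call. = FALSE)
  }
  stopifnot(n_cases >= 1, n_controls >= 1, mean_urv_count > 0,
            sd_urv_count > 0, n_genes > known_set_size,
            known_set_size >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# gamma multiplier giving the target marginal overdispersion of a Poisson
# mixture: Var = mu + mu^2 * s2
.overdispersion_s2 <- function(mean_, sd_) {
  max(0, (sd_^2 - mean_) / mean_^2)
}

#' Simulate a case-control cohort with ground truth
#'
#' Draws per-individual functional-class counts (Poisson around class
#' means, overdispersed by a per-individual gamma multiplier so the
#' marginal coding total matches the configured mean/SD), assigns variants
#' to genes proportionally to lognormal gene weights, and sets case status
#' from a logistic liability on the damaging-URV counts (known genes,
#' non-known genes, planted genes and likely-functional synonymous classes
#' each weighted by the log of their configured odds ratio); the intercept
#' is solved so the expected case fraction matches the configured group
#' sizes. Covariates are sex (Bernoulli 1/2), a Beta-distributed callable
#' fraction and ten standard-normal principal components, none of which
#' enter the liability.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; the same seed reproduces the cohort exactly.
#' @param materialize_variants if `FALSE`, skip building the variant table
#'   (fast path for count-level calibration studies); the returned cohort
#'   then has zero variants but the truth carries the count matrix.
#' @return list with elements `cohort` (an `urv_cohort`), `dhs` (the
#'   `GRanges` DNase-hypersensitive index the DHS-synonymous variants were
#'   placed in), and `truth`: the configuration, seed, liability intercept
#'   and per-individual linear predictor, status, the known/planted gene
#'   ids, the per-individual leaf-class count matrix and the per-individual
#'   damaging counts inside/outside the known set.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1,
                            materialize_variants = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config
  n <- cfg$n_cases + cfg$n_controls
  target_frac <- cfg$n_cases / n

  ## ---- genes ----
  g_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  w <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = cfg$gene_weight_sdlog)
  w <- w / sum(w)
  n_x <- round(cfg$x_gene_fraction * cfg$n_genes)
  chrom_pool <- c(rep("X", n_x),
                  sample(as.character(1:22), cfg$n_genes - n_x,
                         replace = TRUE))
  g_chrom <- sample(chrom_pool)
  g_len <- pmax(300L, as.integer(round(w * cfg$n_genes * 3000)))
  # lay genes sequentially per chromosome with 1 kb gaps, clear of the PARs
  g_start <- integer(cfg$n_genes)
  for (chr in unique(g_chrom)) {
    i <- which(g_chrom == chr)
    offset <- if (chr == "X") 3000000L else 1L
    g_start[i] <- offset + c(0L, cumsum(g_len[i[-length(i)]] + 1000L))
  }
  g_end <- g_start + g_len - 1L
  # DNase-hypersensitive head of each gene body (the DHS index the
  # classifier consumes); DHS-synonymous variants are placed inside it
  dhs_end <- g_start + pmax(30L, as.integer(0.3 * g_len)) - 1L
  dhs <- GenomicRanges::GRanges(g_chrom,
                                IRanges::IRanges(g_start, dhs_end))
  pli <- ifelse(stats::runif(cfg$n_genes) < 0.18,
                stats::rbeta(cfg$n_genes, 20, 1),
                stats::rbeta(cfg$n_genes, 1, 9))
  genes <- data.frame(
    gene = g_ids, pli = round(pli, 4),
    mu_nonsense = cfg$mu_total[["nonsense"]] * w,
    mu_frameshift = cfg$mu_total[["frameshift"]] * w,
    mu_splice = cfg$mu_total[["splice"]] * w,
    mu_missense = cfg$mu_total[["missense"]] * w,
    mu_synonymous = cfg$mu_total[["synonymous"]] * w,
    stringsAsFactors = FALSE
  )
  known <- sample(g_ids, cfg$known_set_size)
  planted <- character(0)
  if (cfg$planted_genes > 0) {
    cand <- setdiff(g_ids[g_chrom != "X"], known)
    cand <- cand[order(-w[match(cand, g_ids)])]
    planted <- cand[seq_len(cfg$planted_genes)]
  }

  ## ---- individuals ----
  ids <- sprintf("S%05d", seq_len(n))
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  karyotype <- ifelse(sex == "male" & stats::runif(n) < cfg$xxy_rate,
                      "XXY", "normal")
  nu <- cfg$callable_mean * (1 - cfg$callable_mean) / cfg$callable_sd^2 - 1
  callable <- stats::rbeta(n, cfg$callable_mean * nu,
                           (1 - cfg$callable_mean) * nu)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("pc", 1:10)))
  s2 <- .overdispersion_s2(cfg$mean_urv_count, cfg$sd_urv_count)
  u <- if (s2 > 0) stats::rgamma(n, shape = 1 / s2, rate = 1 / s2) else
    rep(1, n)

  leaf <- names(cfg$class_props)
  # the doubleton/tripleton promotion below thins the singleton bin, so the
  # draw mean is inflated to keep the post-partition singleton count on
  # target
  mean_eff <- cfg$mean_urv_count /
    (1 - cfg$doubleton_fraction - cfg$tripleton_fraction)
  counts <- vapply(leaf, function(cl) {
    stats::rpois(n, u * mean_eff * cfg$class_props[[cl]])
  }, integer(n))
  noncoding <- stats::rpois(n, u * cfg$noncoding_mean)

  ## ---- gene assignment of coding variants ----
  total_coding <- sum(counts)
  var_ind <- rep.int(seq_len(n), rowSums(counts))
  var_class <- unlist(lapply(seq_len(n), function(i) {
    rep(leaf, counts[i, ])
  }), use.names = FALSE)
  gene_idx <- sample.int(cfg$n_genes, total_coding, replace = TRUE, prob = w)
  var_gene <- g_ids[gene_idx]

  ## ---- liability and status ----
  durv <- var_class %in% c("null", "cd_missense")
  in_known <- var_gene %in% known
  in_planted <- var_gene %in% planted
  tab <- function(sel) {
    out <- integer(n)
    if (any(sel)) {
      agg <- rowsum(rep(1L, sum(sel)), var_ind[sel])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }
  n_durv_known <- tab(durv & in_known)
  n_durv_planted <- tab(durv & in_planted & !in_known)
  n_durv_other <- tab(durv & !in_known & !in_planted)
  n_fcdhs <- tab(var_class == "fcdhs_synonymous")
  n_sr <- tab(var_class == "sr_synonymous")
  eta <- log(cfg$or_durv) * n_durv_other +
    log(cfg$or_known_durv) * n_durv_known +
    log(cfg$or_planted) * n_durv_planted +
    log(cfg$or_fcdhs) * n_fcdhs + log(cfg$or_sr) * n_sr
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - target_frac,
                       c(-30, 10), tol = 1e-10)$root
  status <- ifelse(stats::rbinom(n, 1, stats::plogis(b0 + eta)) == 1,
                   "case", "control")

  samples <- data.frame(id = ids, status = status, sex = sex,
                        karyotype = karyotype,
                        callable_fraction = round(callable, 5), pcs,
                        stringsAsFactors = FALSE)

  truth <- list(
    config = cfg, seed = seed, intercept = b0, eta = eta, status = status,
    known_genes = known, planted_genes = planted,
    class_counts = cbind(counts, noncoding = noncoding),
    n_durv_known = n_durv_known,
    n_durv_nonknown = n_durv_other + n_durv_planted
  )

  if (!materialize_variants) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(.variant_cols),
                               dimnames = list(NULL, .variant_cols)))
    cohort <- urv_cohort(empty, samples, genes)
    return(list(cohort = cohort, dhs = dhs, truth = truth))
  }

  ## ---- materialize variant records ----
  build_block <- function(ind, class, gidx, db_flag) {
    m <- length(ind)
    if (!m) return(NULL)
    gs <- g_start[gidx]; ge <- g_end[gidx]; gd <- dhs_end[gidx]
    pos <- as.integer(gs + floor(stats::runif(m) * (ge - gs + 1)))
    fc <- class == "fcdhs_synonymous"
    pos[fc] <- as.integer(gs[fc] +
                            floor(stats::runif(sum(fc)) *
                                    (gd[fc] - gs[fc] + 1)))
    osy <- class == "other_synonymous"
    pos[osy] <- as.integer(gd[osy] + 1L +
                             floor(stats::runif(sum(osy)) *
                                     pmax(1L, ge[osy] - gd[osy])))
    effect <- character(m)
    effect[class == "null"] <- sample(c("stop_gained", "frameshift_variant",
                                        "splice_donor_variant",
                                        "splice_acceptor_variant"),
                                      sum(class == "null"), replace = TRUE)
    effect[class %in% c("cd_missense", "other_moderate")] <- "missense_variant"
    inframe <- class == "other_moderate" & stats::runif(m) < 0.1
    effect[inframe] <- "inframe_deletion"
    effect[class %in% c("fcdhs_synonymous", "sr_synonymous",
                        "other_synonymous")] <- "synonymous_variant"
    effect[class == "noncoding"] <- "intron_variant"
    impact <- c(null = "HIGH", cd_missense = "MODERATE",
                other_moderate = "MODERATE", fcdhs_synonymous = "LOW",
                sr_synonymous = "LOW", other_synonymous = "LOW",
                noncoding = "MODIFIER")[class]
    preds <- matrix(NA_character_, m, 7,
                    dimnames = list(NULL, .prediction_cols))
    is_mis <- effect == "missense_variant"
    cd <- class == "cd_missense"
    preds[cd, ] <- "D"
    om <- is_mis & !cd
    if (any(om)) {
      pm <- matrix(sample(c("D", "T"), sum(om) * 7, replace = TRUE,
                          prob = c(0.4, 0.6)), ncol = 7)
      # guarantee at least one tolerated call so the consensus fails
      pm[cbind(seq_len(sum(om)),
               sample.int(7, sum(om), replace = TRUE))] <- "T"
      preds[om, ] <- pm
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L +
                    sample.int(3L, m, replace = TRUE)) %% 4L + 1L]
    chrom <- g_chrom[gidx]
    on_x <- chrom == "X"
    gt <- rep("het", m)
    gt[on_x & sex[ind] == "male" & karyotype[ind] == "normal"] <- "hom"
    data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      gene = g_ids[gidx], effect = effect, impact = unname(impact),
      stringsAsFactors = FALSE,
      sift = preds[, 1], pph2_var = preds[, 2], pph2_div = preds[, 3],
      lrt = preds[, 4], mutation_taster = preds[, 5],
      mutation_assessor = preds[, 6], provean = preds[, 7],
      splice_region = as.integer(class == "sr_synonymous"),
      in_exac = as.integer(db_flag), in_esp = 0L, in_tommo = 0L,
      carriers = paste(ids[ind], gt, sep = ":")
    )
  }

  coding_block <- build_block(var_ind, var_class, gene_idx, FALSE)

  nc_total <- sum(noncoding)
  nc_ind <- rep.int(seq_len(n), noncoding)
  nc_gidx <- sample.int(cfg$n_genes, nc_total, replace = TRUE, prob = w)
  nc_block <- build_block(nc_ind, rep("noncoding", nc_total), nc_gidx, FALSE)

  n_db <- stats::rpois(1, n * cfg$mean_urv_count * cfg$db_present_rate)
  db_block <- NULL
  if (n_db > 0) {
    db_ind <- sample.int(n, n_db, replace = TRUE)
    db_class <- sample(leaf, n_db, replace = TRUE,
                       prob = unlist(cfg$class_props))
    db_gidx <- sample.int(cfg$n_genes, n_db, replace = TRUE, prob = w)
    db_block <- build_block(db_ind, db_class, db_gidx, TRUE)
  }

  variants <- rbind(coding_block, nc_block, db_block)

  # promote a fraction of autosomal coding singletons to doubleton/tripleton
  promotable <- which(variants$chrom != "X" & variants$in_exac == 0L &
                        variants$impact != "MODIFIER")
  n2 <- round(cfg$doubleton_fraction * length(promotable))
  n3 <- round(cfg$tripleton_fraction * length(promotable))
  if (n2 + n3 > 0 && length(promotable) > 1 && n > 1) {
    pick <- sample(promotable, min(n2 + n3, length(promotable)))
    first_id <- sub(":.*$", "", variants$carriers[pick])
    draw_extra <- function(avoid) {
      extra <- sample(ids, length(avoid), replace = TRUE)
      while (any(clash <- extra == avoid)) {
        extra[clash] <- sample(ids, sum(clash), replace = TRUE)
      }
      extra
    }
    extra1 <- draw_extra(first_id)
    variants$carriers[pick] <- paste0(variants$carriers[pick], ",",
                                      extra1, ":het")
    if (n3 > 0 && length(pick) > n2) {
      trip <- (n2 + 1):length(pick)
      extra2 <- draw_extra(extra1[trip])
      variants$carriers[pick[trip]] <- paste0(variants$carriers[pick[trip]],
                                              ",", extra2, ":het")
    }
  }

  cohort <- urv_cohort(variants, samples, genes)
  list(cohort = cohort, dhs = dhs, truth = truth)
}

#' Simulate per-gene de novo mutation counts in trios
#'
#' Counts are Poisson with mean `(mu_null + mu_cd_missense) * 2 * n_trios`,
#' multiplied by `fold` for the enriched genes.
#'
#' @param gene_infos gene table (as in an `urv_cohort`).
#' @param n_trios number of trios.
#' @param enriched_genes character vector of gene ids with elevated rates.
#' @param fold rate multiplier for enriched genes.
#' @param cd_fraction see [damaging_rate()].
#' @param seed optional RNG seed.
#' @return data.frame `gene`, `lambda_` (null expectation, fold excluded),
#'   `fold`, `k` (simulated damaging DNM count).
#' @export
simulate_trio_dnms <- function(gene_infos, n_trios, enriched_genes = NULL,
                               fold = 1, cd_fraction = 203 / 1252,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu_null <- gene_infos$mu_nonsense + gene_infos$mu_frameshift +
    gene_infos$mu_splice
  mu_cd <- gene_infos$mu_missense * cd_fraction
  lambda_ <- (mu_null + mu_cd) * 2 * n_trios
  fold_g <- ifelse(gene_infos$gene %in% enriched_genes, fold, 1)
  data.frame(gene = gene_infos$gene, lambda_ = lambda_, fold = fold_g,
             k = stats::rpois(nrow(gene_infos), lambda_ * fold_g),
             stringsAsFactors = FALSE)
}

#' Simulate a gene x tissue expression matrix
#'
#' Log-normal TPM values; genes listed in `elevated_genes` get their
#' expression multiplied by `exp(brain_bias)` in the brain tissues,
#' emulating modifier genes preferentially expressed in brain.
#'
#' @param gene_ids character vector of gene ids (matrix rows).
#' @param tissues character vector of tissue names (matrix columns).
#' @param brain_labels subset of `tissues` forming the brain group.
#' @param elevated_genes genes with brain-biased expression.
#' @param brain_bias log-scale expression shift in brain tissues (default
#'   1.5, about a 4.5-fold elevation).
#' @param meanlog,sdlog baseline log-normal parameters.
#' @param seed optional RNG seed.
#' @return numeric matrix with `gene_ids` rownames and `tissues` colnames.
#' @export
simulate_expression <- function(gene_ids, tissues, brain_labels = NULL,
                                elevated_genes = NULL, brain_bias = 1.5,
                                meanlog = 1.2, sdlog = 1.2, seed = NULL) {
  stopifnot(length(tissues) >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rlnorm(length(gene_ids) * length(tissues),
                            meanlog = meanlog, sdlog = sdlog),
              nrow = length(gene_ids),
              dimnames = list(gene_ids, tissues))
  if (!is.null(elevated_genes) && !is.null(brain_labels) && brain_bias != 0) {
    rows <- gene_ids %in% elevated_genes
    cols <- tissues %in% brain_labels
    m[rows, cols] <- m[rows, cols] * exp(brain_bias)
  }
  m
}
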