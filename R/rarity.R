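# Default pseudoautosomal regions, hg19 coordinates (1-based closed).
.par_hg19 <- data.frame(
  chrom = c("X", "X", "Y", "Y"),
  start = c(60001L, 154931044L, 10001L, 59034050L),
  end = c(2699520L, 155260560L, 2649520L, 59363566L)
)

#' hg19 pseudoautosomal regions
#'
#' @return a `GRanges` with the two PAR intervals on X and Y (hg19).
#' @export
par_regions_hg19 <- function() {
  GenomicRanges::GRanges(.par_hg19$chrom,
                         IRanges::IRanges(.par_hg19$start, .par_hg19$end))
}

#' Classify a genomic site for zygosity qualification
#'
#' Assigns each position to `autosome`, `PAR`, `X_nonPAR`, `Y` or `other`
#' (mitochondrial/unplaced contigs, which the pipeline excludes with a
#' warning).
#'
#' @param chrom,pos chromosome names (chr prefix optional) and 1-based
#'   positions.
#' @param par `GRanges` of pseudoautosomal intervals; defaults to the hg19
#'   regions from [par_regions_hg19()].
#' @return character vector of site classes.
#' @export
classify_site <- function(chrom, pos, par = par_regions_hg19()) {
  chrom <- normalize_chrom(chrom)
  out <- rep("other", length(chrom))
  out[chrom %in% as.character(1:22)] <- "autosome"
  sexchrom <- chrom %in% c("X", "Y")
  if (any(sexchrom)) {
    in_par <- logical(length(chrom))
    if (!is.null(par) && length(par)) {
      in_par[sexchrom] <- point_in_intervals(par, chrom[sexchrom],
                                             pos[sexchrom])
    }
    out[sexchrom & in_par] <- "PAR"
    out[chrom == "X" & !in_par] <- "X_nonPAR"
    out[chrom == "Y" & !in_par] <- "Y"
  }
  out
}

#' Zygosity qualification of a carrier call
#'
#' A carrier call qualifies for the ultra-rare-variant analysis when it is:
#' (1) heterozygous on an autosome; (2) heterozygous in a pseudoautosomal
#' region; (3) heterozygous on non-PAR X in a female or 47,XXY individual;
#' (4) homozygous (i.e. hemizygous) on non-PAR X in a 46,XY male; or
#' (5) homozygous (hemizygous) on Y in a male, XXY included. Pure function
#' of its four arguments; vectorized.
#'
#' @param site_class one of `autosome`, `PAR`, `X_nonPAR`, `Y` (from
#'   [classify_site()]).
#' @param genotype `het`, `hom` or `hemi` (`hemi` is accepted as a synonym
#'   for a homozygous call on a haploid site).
#' @param sex `male` or `female`.
#' @param karyotype `normal` or `XXY`.
#' @return logical vector.
#' @export
qualify_genotype <- function(site_class, genotype, sex, karyotype = "normal") {
  n <- max(length(site_class), length(genotype), length(sex),
           length(karyotype))
  site_class <- rep_len(site_class, n)
  genotype <- rep_len(genotype, n)
  sex <- rep_len(sex, n)
  karyotype <- rep_len(karyotype, n)
  known <- c("autosome", "PAR", "X_nonPAR", "Y")
  if (!all(site_class %in% known)) {
    stop("unknown site class: ",
         paste(unique(setdiff(site_class, known)), collapse = ", "),
         call. = FALSE)
  }
  hemi <- genotype %in% c("hom", "hemi")
  ifelse(site_class == "autosome", genotype == "het",
  ifelse(site_class == "PAR", genotype == "het",
  ifelse(site_class == "X_nonPAR",
         (genotype == "het" & (sex == "female" | karyotype == "XXY")) |
           (hemi & sex == "male" & karyotype == "normal"),
         # Y
         hemi & sex == "male")))
}

#' Partition cohort variants by rarity class
#'
#' Variants present in any selected external population panel (or in an
#' extra exclusion list) are excluded entirely; the remainder are binned by
#' their qualifying cohort allele count into `singleton` (1), `doubleton`
#' (2), `tripleton` (3) or `common_or_excluded` (> 3). The qualifying count
#' only considers carrier calls that pass the zygosity rules of
#' [qualify_genotype()]. Variants on mitochondrial or unplaced contigs are
#' excluded with a warning.
#'
#' Allele counts are computed over the full pre-QC cohort; individuals later
#' removed as count outliers keep their contribution to the rarity labels
#' (QC removes individuals from the analysis, not alleles from the counts).
#'
#' @param cohort an `urv_cohort`.
#' @param db character subset of `c("exac", "esp", "tommo")`: panels whose
#'   presence flag excludes a variant.
#' @param extra_exclude optional character vector of `chrom:pos:ref:alt`
#'   keys (chr prefix optional) to exclude in addition, e.g. a
#'   gnomAD-derived list.
#' @param par PAR intervals passed to [classify_site()].
#' @return the cohort with a `rarity` factor column added to the variant
#'   table and a `"rarity_report"` attribute: counts per bin, the number and
#'   fraction removed by the external panels, and the number removed by the
#'   extra list.
#' @export
partition_by_rarity <- function(cohort, db = c("exac", "esp", "tommo"),
                                extra_exclude = NULL,
                                par = par_regions_hg19()) {
  stopifnot(inherits(cohort, "urv_cohort"))
  db <- match.arg(db, several.ok = TRUE)
  v <- cohort$variants
  n <- nrow(v)
  in_db <- rep(FALSE, n)
  for (panel in db) in_db <- in_db | v[[paste0("in_", panel)]]
  in_extra <- rep(FALSE, n)
  if (!is.null(extra_exclude) && length(extra_exclude)) {
    extra_exclude <- sub("^chr", "", extra_exclude)
    key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
    in_extra <- key %in% extra_exclude
  }
  site <- classify_site(v$chrom, v$pos, par = par)
  off_target <- site == "other"
  if (any(off_target)) {
    warning(sum(off_target),
            " variant(s) on mitochondrial/unplaced contigs excluded")
  }

  # qualifying allele count: carriers passing the zygosity rules
  ct <- carrier_table(cohort)
  s <- cohort$samples
  idx <- match(ct$id, s$id)
  qual <- qualify_genotype(site[ct$variant], ct$genotype,
                           s$sex[idx], s$karyotype[idx])
  contrib <- .allele_contribution(ct$genotype, site[ct$variant])
  qcount <- integer(n)
  agg <- rowsum(as.integer(contrib * qual), ct$variant)
  qcount[as.integer(rownames(agg))] <- agg[, 1]

  rarity <- rep("common_or_excluded", n)
  usable <- !in_db & !in_extra & !off_target
  rarity[usable & qcount == 1L] <- "singleton"
  rarity[usable & qcount == 2L] <- "doubleton"
  rarity[usable & qcount == 3L] <- "tripleton"
  levels <- c("singleton", "doubleton", "tripleton", "common_or_excluded")
  cohort$variants$rarity <- factor(rarity, levels = levels)
  cohort$variants$qualifying_count <- qcount
  attr(cohort, "rarity_report") <- list(
    n_variants = n,
    bins = table(cohort$variants$rarity),
    n_db_excluded = sum(in_db),
    fraction_db_excluded = if (n) sum(in_db) / n else NA_real_,
    n_extra_excluded = sum(in_extra & !in_db),
    fraction_extra_excluded = if (n) sum(in_extra & !in_db) / n else NA_real_
  )
  cohort
}

#' Two-sided Grubbs outlier test statistic and P value
#'
#' @param x numeric vector (length >= 3).
#' @return list with the most extreme index, the Grubbs statistic
#'   `G = max|x - mean| / sd`, and the two-sided P value
#'   `p = 2 N P(T[N-2] > t)` (capped at 1), where
#'   `t = sqrt(N (N-2) G^2 / ((N-1)^2 - N G^2))`.
#' @export
grubbs_test <- function(x) {
  n <- length(x)
  if (n < 3L) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(list(index = NA_integer_, statistic = 0, p = 1))
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  g <- dev[i] / s
  denom <- (n - 1)^2 - n * g^2
  if (denom <= 0) {
    p <- 0   # beyond the attainable maximum of the statistic
  } else {
    t_obs <- sqrt(n * (n - 2) * g^2 / denom)
    p <- min(1, 2 * n * stats::pt(t_obs, df = n - 2, lower.tail = FALSE))
  }
  list(index = i, statistic = g, p = p)
}

#' Iterative Grubbs exclusion of count outliers
#'
#' Repeatedly removes the most extreme value while its two-sided Grubbs test
#' P value is below `alpha` (critical value from the t distribution at
#' `alpha / (2N)`). The procedure sees only the values, never phenotype
#' labels.
#'
#' @param values numeric vector (length >= 3).
#' @param alpha significance threshold (default 0.001).
#' @param iterate if `FALSE`, perform a single pass (at most one exclusion).
#' @return integer indices (into `values`) of the excluded observations, in
#'   removal order.
#' @export
grubbs_outliers <- function(values, alpha = 0.001, iterate = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(values) < 3L) {
    stop("Grubbs outlier exclusion needs at least 3 values", call. = FALSE)
  }
  live <- seq_along(values)
  removed <- integer(0)
  repeat {
    if (length(live) < 3L) break
    res <- grubbs_test(values[live])
    if (is.na(res$index) || res$p >= alpha) break
    removed <- c(removed, live[res$index])
    live <- live[-res$index]
    if (!iterate) break
  }
  removed
}

#' Exclude individuals with outlying URV counts
#'
#' Counts singleton coding URVs per individual (all classes except
#' `noncoding` when classification has run; otherwise every non-MODIFIER
#' variant) and marks Grubbs-test outliers as excluded in the sample table.
#'
#' @param cohort an `urv_cohort` with a `rarity` column (see
#'   [partition_by_rarity()]).
#' @param alpha,iterate passed to [grubbs_outliers()].
#' @return the cohort with `samples$excluded` updated; the per-individual
#'   counts and excluded ids are stored in the `"qc_report"` attribute.
#' @export
exclude_count_outliers <- function(cohort, alpha = 0.001, iterate = TRUE) {
  stopifnot(inherits(cohort, "urv_cohort"))
  if (is.null(cohort$variants$rarity)) {
    stop("run partition_by_rarity() before outlier exclusion", call. = FALSE)
  }
  v <- cohort$variants
  coding <- if (!is.null(v$class)) {
    v$class != "noncoding"
  } else {
    v$impact != "MODIFIER"
  }
  keep <- which(coding & v$rarity == "singleton")
  ct <- carrier_table(cohort)
  ct <- ct[ct$variant %in% keep, ]
  counts <- table(factor(ct$id, levels = cohort$samples$id))
  counts <- as.integer(counts)
  names(counts) <- cohort$samples$id
  out_idx <- grubbs_outliers(counts, alpha = alpha, iterate = iterate)
  cohort$samples$excluded <- seq_len(nrow(cohort$samples)) %in% out_idx
  attr(cohort, "qc_report") <- list(
    counts = counts,
    excluded_ids = cohort$samples$id[out_idx],
    alpha = alpha
  )
  cohort
}
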