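#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided P value by the probability-mass rule: with
#' the table margins fixed, P is the sum of hypergeometric probabilities of
#' all tables whose probability does not exceed that of the observed table
#' (the convention of [stats::fisher.test()]). Implemented directly on the
#' hypergeometric mass so the gene scan can evaluate and cache it cheaply.
#'
#' @param a,b,c_,d nonnegative integer cell counts, rows = groups, columns
#'   = carrier/non-carrier: `a` and `b` are the first row. Vectorized.
#' @return two-sided P value(s) in (0, 1]; an all-zero table gives 1.
#' @export
fisher_two_tailed <- function(a, b, c_, d) {
  n <- max(length(a), length(b), length(c_), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c_ <- rep_len(c_, n); d <- rep_len(d, n)
  if (any(c(a, b, c_, d) < 0) || any(c(a, b, c_, d) != floor(c(a, b, c_, d)))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    m <- a[i] + b[i]       # row 1 total
    nn <- c_[i] + d[i]     # row 2 total
    k <- a[i] + c_[i]      # column 1 total
    if (m + nn == 0L) return(1)
    lo <- max(0L, k - nn)
    hi <- min(k, m)
    x <- lo:hi
    dens <- stats::dhyper(x, m, nn, k)
    d_obs <- dens[x == a[i]]
    # relative tolerance guards against FP noise in equal-mass tables
    sum(dens[dens <= d_obs * (1 + 1e-7)])
  }, 0)
}

#' Gene-based collapsing burden test
#'
#' For every gene with at least one qualifying variant, compares the
#' proportion of cases versus controls carrying one or more variant of the
#' class (default: damaging URVs) by the two-tailed Fisher exact test.
#' Genes carried only by excluded individuals (or with zero carriers in the
#' analysed subset) are dropped: they can never reach significance.
#'
#' @param cohort a classified, partitioned `urv_cohort`.
#' @param cases character vector of case ids to analyse (default: all
#'   non-excluded cases).
#' @param class class label (default `"durv"`).
#' @param exclude_genes genes dropped from the scan (e.g. the known set).
#' @param rarity rarity bin (default `"singleton"`).
#' @param exome_wide_alpha,nominal_alpha significance thresholds for the
#'   `exome_wide` and `nominal` flags (defaults 2.5e-6 = 0.05 / 20,000 and
#'   0.05).
#' @return data.frame: `gene`, `case_carriers`, `control_carriers`,
#'   `n_case`, `n_control`, `or_` (cross-product ratio, 0.5 added to every
#'   cell when any cell is zero), `p`, `exome_wide`, `nominal`; sorted by
#'   `p`.
#' @export
gene_burden_scan <- function(cohort, cases = NULL, class = "durv",
                             exclude_genes = NULL, rarity = "singleton",
                             exome_wide_alpha = 2.5e-6,
                             nominal_alpha = 0.05) {
  stopifnot(inherits(cohort, "urv_cohort"))
  if (is.null(cases)) cases <- included_ids(cohort, "case")
  controls <- included_ids(cohort, "control")
  carriers <- .gene_carriers(cohort, class = class,
                             exclude_genes = exclude_genes, rarity = rarity,
                             ids = c(cases, controls))
  .scan_from_carriers(carriers, cases, controls,
                      exome_wide_alpha = exome_wide_alpha,
                      nominal_alpha = nominal_alpha)
}

# list(gene -> character vector of distinct carrier ids), restricted to ids
.gene_carriers <- function(cohort, class, exclude_genes, rarity, ids) {
  v <- cohort$variants
  if (is.null(v$class)) stop("run classify_variants() first", call. = FALSE)
  keep <- v$class %in% expand_class(class)
  if (!is.null(rarity)) {
    if (is.null(v$rarity)) stop("run partition_by_rarity() first",
                                call. = FALSE)
    keep <- keep & v$rarity %in% rarity
  }
  if (!is.null(exclude_genes)) keep <- keep & !v$gene %in% exclude_genes
  ct <- carrier_table(cohort)
  ct <- ct[keep[ct$variant] & ct$id %in% ids, , drop = FALSE]
  ct$gene <- v$gene[ct$variant]
  lapply(split(ct$id, ct$gene), unique)
}

.scan_from_carriers <- function(carriers, cases, controls,
                                exome_wide_alpha = 2.5e-6,
                                nominal_alpha = 0.05) {
  n_case <- length(cases)
  n_control <- length(controls)
  genes <- names(carriers)
  a <- vapply(carriers, function(ids) sum(ids %in% cases), 0L)
  k <- lengths(carriers)
  cc <- k - a
  keep <- k > 0L
  genes <- genes[keep]; a <- a[keep]; cc <- cc[keep]
  p <- fisher_two_tailed(a, n_case - a, cc, n_control - cc)
  or_ <- .cross_product_or(a, n_case - a, cc, n_control - cc)
  out <- data.frame(gene = genes, case_carriers = as.integer(a),
                    control_carriers = as.integer(cc),
                    n_case = n_case, n_control = n_control,
                    or_ = or_, p = p,
                    exome_wide = p < exome_wide_alpha,
                    nominal = p >= exome_wide_alpha & p < nominal_alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# cross-product OR; 0.5 continuity added to every cell when any cell is 0
.cross_product_or <- function(a, b, c_, d) {
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  h <- ifelse(zero, 0.5, 0)
  ((a + h) * (d + h)) / ((b + h) * (c_ + h))
}

#' Case-control label-shuffling overlap test
#'
#' Evaluates whether the genes reaching nominal significance in the
#' collapsing scan overlap a reference gene set more than expected by
#' chance. Case/control labels are permuted (group sizes preserved
#' exactly), the scan re-run each iteration, and the fraction of nominally
#' significant genes overlapping the reference recorded; the empirical P is
#' the plain fraction of iterations with an overlap fraction at least as
#' large as observed, reported as `< 1/iterations` when no iteration
#' reaches it.
#'
#' @inheritParams gene_burden_scan
#' @param reference_set character vector of reference gene ids (non-empty).
#' @param iterations number of label shuffles (>= 1).
#' @param seed master RNG seed; the same seed reproduces the result
#'   exactly.
#' @return object of class `overlap_permutation`: `observed_overlap_fraction`,
#'   `n_nominal`, `n_overlap`, `null_fractions` (length `iterations`),
#'   `empirical_p`, `p_label`, `iterations`, `seed`.
#' @export
overlap_permutation <- function(cohort, reference_set, iterations = 10000,
                                seed = 1, cases = NULL, class = "durv",
                                exclude_genes = NULL, rarity = "singleton",
                                exome_wide_alpha = 2.5e-6,
                                nominal_alpha = 0.05) {
  stopifnot(iterations >= 1)
  if (is.null(reference_set) || !length(reference_set)) {
    stop("reference set must be non-empty", call. = FALSE)
  }
  if (is.null(cases)) cases <- included_ids(cohort, "case")
  controls <- included_ids(cohort, "control")
  ids <- c(cases, controls)
  carriers <- .gene_carriers(cohort, class = class,
                             exclude_genes = exclude_genes, rarity = rarity,
                             ids = ids)
  genes <- names(carriers)
  if (!any(genes %in% reference_set)) {
    warning("reference set is disjoint from all genes carrying variants")
  }

  observed <- .scan_from_carriers(carriers, cases, controls,
                                  exome_wide_alpha, nominal_alpha)
  obs <- .overlap_fraction(observed, reference_set)

  # fast permutation machinery: per-gene carrier index lists + cached
  # Fisher P lookup keyed by the (fixed) per-gene carrier total
  id_index <- seq_along(ids)
  names(id_index) <- ids
  carrier_idx <- lapply(carriers, function(x) unname(id_index[x]))
  gene_rep <- rep.int(seq_along(carrier_idx), lengths(carrier_idx))
  flat_idx <- unlist(carrier_idx, use.names = FALSE)
  k_total <- lengths(carrier_idx)
  n_case <- length(cases)
  n_control <- length(controls)
  p_lookup <- lapply(sort(unique(k_total)), function(k) {
    out <- rep(NA_real_, k + 1)
    av <- max(0, k - n_control):min(k, n_case)
    out[av + 1] <- fisher_two_tailed(av, n_case - av, k - av,
                                     n_control - (k - av))
    out
  })
  names(p_lookup) <- as.character(sort(unique(k_total)))
  in_ref <- genes %in% reference_set

  set.seed(seed)
  null_fractions <- vapply(seq_len(iterations), function(i) {
    perm_case <- logical(length(ids))
    perm_case[sample.int(length(ids), n_case)] <- TRUE
    a <- integer(length(carrier_idx))
    agg <- rowsum(as.integer(perm_case[flat_idx]), gene_rep)
    a[as.integer(rownames(agg))] <- agg[, 1]
    p <- vapply(seq_along(a), function(g) {
      p_lookup[[as.character(k_total[g])]][a[g] + 1L]
    }, 0)
    nominal <- p >= exome_wide_alpha & p < nominal_alpha
    if (!any(nominal)) return(0)
    sum(nominal & in_ref) / sum(nominal)
  }, 0)

  exceed <- sum(null_fractions >= obs$fraction)
  empirical_p <- exceed / iterations
  structure(list(
    observed_overlap_fraction = obs$fraction,
    n_nominal = obs$n_nominal,
    n_overlap = obs$n_overlap,
    null_fractions = null_fractions,
    empirical_p = empirical_p,
    p_label = if (exceed == 0L) paste0("< ", format(1 / iterations)) else
      format(empirical_p),
    iterations = iterations,
    seed = seed
  ), class = "overlap_permutation")
}

.overlap_fraction <- function(scan, reference_set) {
  nom <- scan$gene[scan$nominal]
  n_overlap <- sum(nom %in% reference_set)
  list(fraction = if (length(nom)) n_overlap / length(nom) else 0,
       n_nominal = length(nom), n_overlap = n_overlap)
}

#' Observed overlap of nominally significant genes with a reference set
#'
#' @param scan data.frame from [gene_burden_scan()].
#' @param reference_set character vector of gene ids.
#' @return list with `fraction` (0 when no gene is nominally significant),
#'   `n_nominal` and `n_overlap`.
#' @export
observed_overlap <- function(scan, reference_set) {
  .overlap_fraction(scan, reference_set)
}

#' @export
print.overlap_permutation <- function(x, ...) {
  cat(sprintf("Label-shuffling overlap test (%d iterations, seed %s)\n",
              x$iterations, format(x$seed)))
  cat(sprintf("  observed: %d / %d nominally significant genes in reference (%.1f%%)\n",
              x$n_overlap, x$n_nominal, 100 * x$observed_overlap_fraction))
  cat("  empirical P", if (startsWith(x$p_label, "<")) "" else "=",
      x$p_label, "\n")
  invisible(x)
}
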