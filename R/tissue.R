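#' Expression-derived gene sets (TPM threshold)
#'
#' For each tissue, the set of genes with expression strictly above the
#' threshold (default TPM > 10: moderate-to-high expression).
#'
#' @param matrix_ numeric gene x tissue matrix of TPM values (rownames =
#'   gene ids, colnames = tissue names; no negative entries).
#' @param threshold strictly positive expression cutoff.
#' @return named list: tissue -> character vector of gene ids.
#' @export
tpm_gene_sets <- function(matrix_, threshold = 10) {
  stopifnot(threshold > 0)
  if (is.null(dim(matrix_)) || nrow(matrix_) == 0L || ncol(matrix_) == 0L) {
    stop("expression matrix is empty", call. = FALSE)
  }
  if (any(matrix_ < 0)) stop("TPM values must be nonnegative", call. = FALSE)
  if (is.null(rownames(matrix_)) || is.null(colnames(matrix_))) {
    stop("expression matrix needs gene rownames and tissue colnames",
         call. = FALSE)
  }
  sets <- lapply(seq_len(ncol(matrix_)), function(j) {
    rownames(matrix_)[matrix_[, j] > threshold]
  })
  names(sets) <- colnames(matrix_)
  sets
}

#' Tissue-wise gene-set burden scan
#'
#' Runs the covariate-adjusted logistic burden test of [fit_burden()] once
#' per tissue, treating the tissue's gene set as the gene restriction, for
#' a designated case subset versus all controls.
#'
#' @param cohort a classified, partitioned `urv_cohort`.
#' @param gene_sets named list tissue -> gene ids (e.g. from
#'   [tpm_gene_sets()]).
#' @param cases case ids to contrast with controls (default: all
#'   non-excluded cases).
#' @param class class label (default `"durv"`).
#' @param exclude_genes genes removed from every set (e.g. the known
#'   disease genes when scanning their complement).
#' @param ... passed to [fit_burden()].
#' @return data.frame: `tissue`, `n_genes`, `n_variants`, `or_`, `p`,
#'   `direction` (`enriched` for OR > 1 else `depleted`).
#' @export
tissue_scan <- function(cohort, gene_sets, cases = NULL, class = "durv",
                        exclude_genes = NULL, ...) {
  stopifnot(length(gene_sets) >= 1)
  if (is.null(cases)) cases <- included_ids(cohort, "case")
  controls <- included_ids(cohort, "control")
  rows <- lapply(names(gene_sets), function(tis) {
    gs <- setdiff(gene_sets[[tis]], exclude_genes)
    counts <- suppressWarnings(
      count_urvs(cohort, class = class, gene_set = gs)
    )
    counts_sub <- counts[names(counts) %in% c(cases, controls)]
    attr(counts_sub, "n_variants") <- attr(counts, "n_variants")
    fit <- fit_burden(counts_sub, cohort$samples, ...)
    data.frame(tissue = tis, n_genes = length(gs),
               n_variants = fit$n_variants %||% NA_integer_,
               or_ = fit$or_, p = fit$p,
               direction = if (fit$or_ > 1) "enriched" else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Directional rank ordering of tissue results
#'
#' Orders tissues so that the strongest case-enrichment signals rank first
#' and the strongest depletion signals rank last: (1) enriched (OR > 1)
#' tissues by ascending P, then (2) the weakest enriched tissues; then (3)
#' the weakest depleted (OR < 1) tissues, and (4) the most significantly
#' depleted tissues last. Equivalently: the enriched block ascending in P,
#' the depleted block descending in P (descending signed z). Tissues with
#' OR exactly 1 close the enriched block. Ties break by tissue name, so the
#' order is a deterministic total order regardless of input order.
#'
#' @param results data.frame from [tissue_scan()] (needs `tissue`, `or_`,
#'   `p`).
#' @return the same data.frame, sorted, with an integer `rank` column
#'   (1 = most enriched).
#' @export
directional_sort <- function(results) {
  stopifnot(all(c("tissue", "or_", "p") %in% names(results)))
  tier <- ifelse(results$or_ > 1, 1L, ifelse(results$or_ == 1, 2L, 3L))
  key_p <- ifelse(tier == 3L, -results$p, results$p)
  ord <- order(tier, key_p, results$tissue)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Brain versus other tissues rank contrast
#'
#' Two-tailed Wilcoxon rank-sum test comparing the directional ranks of
#' brain tissues against all other tissues: exact for small groups (both
#' sizes <= 25; ranks are untied by construction), normal approximation
#' with continuity correction otherwise.
#'
#' @param ranked data.frame from [directional_sort()].
#' @param brain_labels character vector of tissue names forming the brain
#'   group (must be a non-empty proper subset of the tissues).
#' @return the two-sided P value, with attributes `"W"` (the rank-sum
#'   statistic) and the two group sizes.
#' @export
brain_vs_other <- function(ranked, brain_labels) {
  stopifnot(all(c("tissue", "rank") %in% names(ranked)))
  is_brain <- ranked$tissue %in% brain_labels
  if (!any(is_brain) || all(is_brain)) {
    stop("both tissue groups must be non-empty", call. = FALSE)
  }
  b <- ranked$rank[is_brain]
  o <- ranked$rank[!is_brain]
  exact <- length(b) <= 25 && length(o) <= 25
  res <- stats::wilcox.test(b, o, alternative = "two.sided",
                            exact = exact, correct = TRUE)
  p <- res$p.value
  attr(p, "W") <- unname(res$statistic)
  attr(p, "n_brain") <- length(b)
  attr(p, "n_other") <- length(o)
  p
}
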