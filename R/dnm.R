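#' Per-gene damaging de novo mutation rates
#'
#' The per-haploid null rate is the sum of the nonsense, frameshift and
#' splice-site rates; the consensus-damaging missense rate is the total
#' missense rate scaled by the fraction of de novo missense mutations in
#' unaffected-sibling control trios that meet the seven-algorithm damaging
#' consensus (default 203/1252).
#'
#' @param gene_info one row of the gene table (or any list with
#'   `mu_nonsense`, `mu_frameshift`, `mu_splice`, `mu_missense`).
#' @param cd_fraction scaling applied to the missense rate, in (0, 1].
#' @return named numeric vector `c(mu_null, mu_cd_missense)`.
#' @export
damaging_rate <- function(gene_info, cd_fraction = 203 / 1252) {
  stopifnot(cd_fraction > 0, cd_fraction <= 1)
  comp <- c("mu_nonsense", "mu_frameshift", "mu_splice", "mu_missense")
  for (cc in comp) {
    val <- gene_info[[cc]]
    if (is.null(val) || length(val) != 1L || is.na(val)) {
      stop("missing mutation-rate component: ", cc, call. = FALSE)
    }
  }
  mu_null <- gene_info$mu_nonsense + gene_info$mu_frameshift +
    gene_info$mu_splice
  c(mu_null = unname(mu_null),
    mu_cd_missense = unname(gene_info$mu_missense * cd_fraction))
}

#' Poisson upper-tail probability P(X >= k)
#'
#' @param lambda_ expected count (>= 0).
#' @param k observed count (nonnegative integer).
#' @return `P(X >= k)` under Poisson(`lambda_`); 1 for `k = 0`, 0 for
#'   `lambda_ = 0, k >= 1`. Evaluated via the regularized upper incomplete
#'   gamma function, which is numerically stable for small `lambda_`.
#' @export
poisson_tail <- function(lambda_, k) {
  if (any(lambda_ < 0) || any(k < 0) || any(k != floor(k))) {
    stop("lambda_ must be >= 0 and k a nonnegative integer", call. = FALSE)
  }
  ifelse(k == 0, 1, stats::ppois(k - 1, lambda_, lower.tail = FALSE))
}

#' Per-gene de novo mutation enrichment test
#'
#' Composes the damaging-rate construction, the expected count
#' `lambda = (mu_null + mu_cd_missense) * 2 * n_trios`, the Poisson upper
#' tail at the observed count, and Bonferroni corrections over the number
#' of testable genes and over the number of disease subtypes.
#'
#' @param gene gene id (label only).
#' @param k_observed observed number of damaging de novo mutations.
#' @param n_trios number of proband-parent trios screened.
#' @param gene_info per-gene mutation rates (see [damaging_rate()]).
#' @param n_testable_genes family size for the gene-count correction
#'   (conventionally the number of genes with at least one damaging URV in
#'   the cohort).
#' @param n_subtypes family size for the subtype correction.
#' @param cd_fraction see [damaging_rate()].
#' @return object of class `dnm_test` (also a one-row data.frame): `gene`,
#'   `n_trios`, `mu_null`, `mu_cd_missense`, `lambda_`, `k_observed`, `p`,
#'   `p_gene_corrected`, `p_subtype_corrected`.
#' @export
dnm_enrichment <- function(gene, k_observed, n_trios, gene_info,
                           n_testable_genes = NA, n_subtypes = NA,
                           cd_fraction = 203 / 1252) {
  stopifnot(n_trios >= 0, k_observed >= 0)
  mu <- damaging_rate(gene_info, cd_fraction)
  lambda_ <- sum(mu) * 2 * n_trios
  p <- poisson_tail(lambda_, k_observed)
  out <- data.frame(
    gene = gene, n_trios = n_trios,
    mu_null = mu[["mu_null"]], mu_cd_missense = mu[["mu_cd_missense"]],
    lambda_ = lambda_, k_observed = k_observed, p = p,
    p_gene_corrected = if (is.na(n_testable_genes)) NA_real_ else
      min(1, p * n_testable_genes),
    p_subtype_corrected = if (is.na(n_subtypes)) NA_real_ else
      min(1, p * n_subtypes),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dnm_test", class(out))
  out
}

#' @export
print.dnm_test <- function(x, ...) {
  cat(sprintf("DNM enrichment, %s: lambda = %.4g over %d trios, observed %d, P(X >= k) = %.3g\n",
              x$gene, x$lambda_, x$n_trios, x$k_observed, x$p))
  if (!is.na(x$p_gene_corrected)) {
    cat(sprintf("  gene-count corrected P = %.3g\n", x$p_gene_corrected))
  }
  if (!is.na(x$p_subtype_corrected)) {
    cat(sprintf("  subtype corrected P = %.3g\n", x$p_subtype_corrected))
  }
  invisible(x)
}

#' Invert the Poisson tail for its rate
#'
#' Solves `P(X >= k; lambda) = p_target` for `lambda` by bracketed root
#' finding on the log scale (relative tolerance 1e-10). Used to recover an
#' implied per-cohort expected count from a published tail probability, so
#' that the same rate can be transferred to a different cohort size.
#'
#' @param p_target target tail probability in (0, 1).
#' @param k observed count (>= 1).
#' @return the unique `lambda` with `poisson_tail(lambda, k) == p_target`.
#' @export
invert_lambda <- function(p_target, k) {
  stopifnot(p_target > 0, p_target < 1, k >= 1, k == floor(k))
  # series initial guess: P(X >= k) ~ lambda^k / k! for small lambda
  guess <- (p_target * factorial(min(k, 20))) ^ (1 / k)
  lo <- guess / 100
  hi <- max(guess * 100, 1)
  f <- function(loglam) poisson_tail(exp(loglam), k) - p_target
  while (f(log(hi)) < 0) hi <- hi * 10
  while (f(log(lo)) > 0) lo <- lo / 10
  root <- stats::uniroot(f, lower = log(lo), upper = log(hi),
                         tol = 1e-14)$root
  exp(root)
}
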