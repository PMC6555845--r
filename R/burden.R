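#' Per-individual URV counts
#'
#' Counts qualifying variants of a functional class per (non-excluded)
#' individual, optionally restricted to a gene set and to a rarity bin.
#' A variant contributes one count to each of its carriers.
#'
#' @param cohort a classified `urv_cohort` (see [classify_variants()]).
#' @param class leaf or aggregate class label (see [expand_class()]);
#'   default `"durv"` = null + consensus-damaging missense.
#' @param gene_set optional character vector of gene ids; `NULL` = all
#'   genes.
#' @param exclude_genes optional character vector of gene ids to drop
#'   (e.g. the known-disease-gene set when analysing the complement).
#' @param rarity rarity bin to count (default `"singleton"`); `NULL`
#'   counts across all bins.
#' @return named integer vector over all non-excluded individuals, with
#'   attribute `"n_variants"` = number of distinct variants counted.
#' @export
count_urvs <- function(cohort, class = "durv", gene_set = NULL,
                       exclude_genes = NULL, rarity = "singleton") {
  stopifnot(inherits(cohort, "urv_cohort"))
  if (is.null(cohort$variants$class)) {
    stop("run classify_variants() first", call. = FALSE)
  }
  v <- cohort$variants
  keep <- v$class %in% expand_class(class)
  if (!is.null(rarity)) {
    if (is.null(v$rarity)) stop("run partition_by_rarity() first",
                                call. = FALSE)
    keep <- keep & v$rarity %in% rarity
  }
  if (!is.null(gene_set)) keep <- keep & v$gene %in% gene_set
  if (!is.null(exclude_genes)) keep <- keep & !v$gene %in% exclude_genes
  ids <- included_ids(cohort)
  ct <- carrier_table(cohort)
  ct <- ct[keep[ct$variant] & ct$id %in% ids, , drop = FALSE]
  counts <- table(factor(ct$id, levels = ids))
  out <- as.integer(counts)
  names(out) <- ids
  n_var <- length(unique(ct$variant))
  if (n_var == 0L) {
    warning("no variants match class '", class, "' in the requested set; ",
            "returning a zero count vector")
  }
  attr(out, "n_variants") <- n_var
  out
}

#' Covariate-adjusted logistic burden test
#'
#' Fits a maximum-likelihood logistic regression of case/control status on
#' the per-individual URV count plus covariates (default: sex coded 0/1,
#' proportion of callable loci, and the first ten principal components) and
#' reports the odds ratio for one additional URV with a Wald 95% confidence
#' interval and two-sided P value.
#'
#' When every carrier (count > 0) belongs to a single phenotype group the
#' count coefficient is not identified (complete separation); see
#' [handle_separation()], applied automatically unless `separation =
#' "none"`.
#'
#' @param counts named integer vector from [count_urvs()] (names = sample
#'   ids).
#' @param samples the cohort sample table (or an `urv_cohort`).
#' @param covariates character vector of covariate column names; `sex` is
#'   recoded male = 1, female = 0.
#' @param test `"wald"` (default) for the coefficient z-test or `"lrt"`
#'   for a likelihood-ratio P value (the CI stays Wald-based).
#' @param separation `"pseudo_count"` (default) applies the one-variant
#'   pseudo-count fix on separation, `"none"` refuses to fix and fits as-is.
#' @return an object of class `burden_fit` with elements `beta`, `or_`,
#'   `ci95`, `p`, `se`, `n_case`, `n_control`, `n_variants`, `converged`,
#'   `separation_flag`, `p_is_upper_bound`, and the underlying `glm` fit.
#' @export
fit_burden <- function(counts, samples,
                       covariates = c("sex", "callable_fraction",
                                      paste0("pc", 1:10)),
                       test = c("wald", "lrt"),
                       separation = c("pseudo_count", "none")) {
  test <- match.arg(test)
  separation <- match.arg(separation)
  if (inherits(samples, "urv_cohort")) samples <- samples$samples
  if (is.null(names(counts))) {
    stop("counts must be named by sample id", call. = FALSE)
  }
  s <- samples[match(names(counts), samples$id), , drop = FALSE]
  if (anyNA(s$id)) stop("counts contain ids absent from the manifest",
                        call. = FALSE)
  y <- as.integer(s$status == "case")
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one case and one control", call. = FALSE)
  }

  x <- as.numeric(counts)
  carriers <- x > 0
  sep <- any(carriers) &&
    (all(y[carriers] == 1L) || all(y[carriers] == 0L))
  separation_flag <- FALSE
  p_is_upper_bound <- FALSE
  if (sep && separation == "pseudo_count") {
    if (all(y[carriers] == 1L)) {
      pool <- which(y == 0L)
    } else {
      pool <- which(y == 1L)
    }
    if (!length(pool)) {
      stop("unrecoverable separation: no individuals in the opposite group",
           call. = FALSE)
    }
    # deterministic rule: first id of the opposite group in lexicographic order
    target <- pool[order(s$id[pool])][1]
    x[target] <- x[target] + 1
    separation_flag <- TRUE
    p_is_upper_bound <- TRUE
  }

  df <- data.frame(y = y, count = x)
  for (cv in covariates) {
    col <- s[[cv]]
    if (is.null(col)) stop("covariate '", cv, "' absent from manifest",
                           call. = FALSE)
    if (cv == "sex") col <- as.integer(col == "male")
    df[[cv]] <- col
  }
  if (anyNA(df)) stop("covariates contain missing values", call. = FALSE)

  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100))
  beta <- stats::coef(fit)["count"]
  se <- sqrt(stats::vcov(fit)["count", "count"])
  z <- beta / se
  p_wald <- 2 * stats::pnorm(-abs(z))
  p <- p_wald
  if (test == "lrt") {
    fit0 <- stats::glm(y ~ . - count, data = df, family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100))
    p <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
  }
  zq <- stats::qnorm(0.975)
  structure(list(
    beta = unname(beta),
    or_ = exp(unname(beta)),
    se = unname(se),
    ci95 = exp(unname(beta) + c(-1, 1) * zq * unname(se)),
    p = unname(p),
    test = test,
    n_case = sum(y),
    n_control = sum(1L - y),
    n_variants = attr(counts, "n_variants"),
    converged = fit$converged,
    separation_flag = separation_flag,
    p_is_upper_bound = p_is_upper_bound,
    fit = fit
  ), class = "burden_fit")
}

#' Pseudo-count refit under complete separation
#'
#' When all carriers of a variant class share one phenotype group, the
#' logistic burden test is degenerate. Following the pipeline's convention,
#' one variant is added to the count of a single individual of the opposite
#' group (deterministically the first such id in lexicographic order), the
#' model is refit, and the resulting P value is reported as an upper bound
#' (`p_is_upper_bound = TRUE`). Without separation the fit passes through
#' unchanged.
#'
#' @inheritParams fit_burden
#' @return a `burden_fit`.
#' @export
handle_separation <- function(counts, samples,
                              covariates = c("sex", "callable_fraction",
                                             paste0("pc", 1:10))) {
  fit_burden(counts, samples, covariates = covariates,
             separation = "pseudo_count")
}

#' @export
print.burden_fit <- function(x, ...) {
  cat("Logistic burden test (", x$test, "): ",
      x$n_case, " cases / ", x$n_control, " controls",
      if (!is.null(x$n_variants)) paste0(", ", x$n_variants, " variants"),
      "\n", sep = "")
  cat(sprintf("  OR per additional URV = %.4g (95%% CI %.4g-%.4g), P %s %.3g\n",
              x$or_, x$ci95[1], x$ci95[2],
              if (x$p_is_upper_bound) "<" else "=", x$p))
  if (x$separation_flag) {
    cat("  complete separation: one pseudo-variant added to the opposite group\n")
  }
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  invisible(x)
}

#' @export
summary.burden_fit <- function(object, ...) {
  print(object)
  cat("\nFull model coefficients:\n")
  stats::printCoefmat(stats::coef(summary(object$fit)))
  invisible(object)
}

#' @export
coef.burden_fit <- function(object, ...) {
  c(count = object$beta)
}

#' @export
confint.burden_fit <- function(object, parm = "count", level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(object$beta + c(-1, 1) * zq * object$se, nrow = 1,
              dimnames = list("count", c("lower", "upper")))
  m
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`) and Benjamini-Hochberg step-up adjustment over
#' a family of `m` hypotheses, via [stats::p.adjust()].
#'
#' @param p numeric vector of raw P values in (0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param m family size; defaults to `length(p)`. Supplying `m` larger than
#'   `length(p)` corrects a subset of a wider family.
#' @return adjusted P values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop("P values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni",
                  n = m)
}

#' Build a burden-analysis manifest
#'
#' Enumerates the (variant class, gene set, case subset) combinations of a
#' burden analysis; its row count is the family size used for
#' multiple-testing correction.
#'
#' @param classes character vector of class labels.
#' @param gene_sets named list of gene-id vectors (`NULL` entry = all
#'   genes).
#' @param subsets named list of case-id vectors (`NULL` entry = all cases).
#' @return data.frame with columns `test_id`, `class`, `gene_set`,
#'   `subset`, and attributes carrying the actual sets.
#' @export
burden_manifest <- function(classes, gene_sets = list(all = NULL),
                            subsets = list(all_cases = NULL)) {
  grid <- expand.grid(class = classes, gene_set = names(gene_sets),
                      subset = names(subsets), stringsAsFactors = FALSE)
  grid <- data.frame(test_id = seq_len(nrow(grid)), grid)
  attr(grid, "gene_sets") <- gene_sets
  attr(grid, "subsets") <- subsets
  grid
}

#' Run a manifest of burden tests
#'
#' Executes every (class, gene set, case subset) test of a manifest against
#' the controls and adjusts the P values over the manifest's family size
#' with both Bonferroni and Benjamini-Hochberg.
#'
#' @param cohort a classified, partitioned `urv_cohort`.
#' @param manifest from [burden_manifest()].
#' @param exclude_genes optional genes dropped from every test.
#' @param ... passed to [fit_burden()].
#' @return data.frame: one row per test with `or_`, `ci_low`, `ci_high`,
#'   `p`, `p_bonferroni`, `p_bh`, `n_variants`, `separation_flag`,
#'   `p_is_upper_bound`.
#' @export
run_burden_tests <- function(cohort, manifest, exclude_genes = NULL, ...) {
  gene_sets <- attr(manifest, "gene_sets")
  subsets <- attr(manifest, "subsets")
  controls <- included_ids(cohort, "control")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    cls <- manifest$class[i]
    gs <- gene_sets[[manifest$gene_set[i]]]
    cases <- subsets[[manifest$subset[i]]]
    if (is.null(cases)) cases <- included_ids(cohort, "case")
    counts <- suppressWarnings(
      count_urvs(cohort, class = cls, gene_set = gs,
                 exclude_genes = exclude_genes)
    )
    counts_sub <- counts[names(counts) %in% c(cases, controls)]
    attr(counts_sub, "n_variants") <- attr(counts, "n_variants")
    fit <- fit_burden(counts_sub, cohort$samples, ...)
    data.frame(test_id = manifest$test_id[i], class = cls,
               gene_set = manifest$gene_set[i], subset = manifest$subset[i],
               n_variants = fit$n_variants %||% NA_integer_,
               or_ = fit$or_, ci_low = fit$ci95[1], ci_high = fit$ci95[2],
               p = fit$p, separation_flag = fit$separation_flag,
               p_is_upper_bound = fit$p_is_upper_bound)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- adjust_pvalues(out$p, "bonferroni", m = nrow(out))
  out$p_bh <- adjust_pvalues(out$p, "bh", m = nrow(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
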