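#' Assign pathogenic-URV (pURV) status to cases
#'
#' Among cases carrying a damaging URV (dURV: null or consensus-damaging
#' missense) in the known-disease-gene set, a variant is promoted to
#' convincingly pathogenic (pURV) when its inheritance qualifies:
#' \enumerate{
#'   \item autosomal known-gene dURV confirmed de novo (a de novo call with
#'     mosaicism in one parent also qualifies and is flagged);
#'   \item hemizygous dURV in an X-linked recessive gene (default `PIGA`,
#'     `ARX`, `IQSEC2`, `ARHGEF9`), maternally transmitted or de novo;
#'   \item heterozygous dURV in a female-specific X-linked gene (default
#'     `PCDH19`), paternally transmitted or de novo;
#'   \item dURV in any other X-chromosome known gene confirmed de novo.
#' }
#' Carriers whose dURV has no qualifying inheritance (inherited from an
#' unaffected parent, untested, or mosaic in the proband) keep
#' `carries_durv_in_known = TRUE` with no pURV.
#'
#' @param cohort a classified, partitioned `urv_cohort`.
#' @param known_genes character vector: the established disease gene set.
#' @param trio_calls data.frame of trio inheritance labels with columns
#'   `id`, `chrom`, `pos`, `ref`, `alt`, `inheritance` (one of `de_novo`,
#'   `maternal`, `paternal`, `unknown`, `mosaic_parent`, `mosaic_proband`).
#'   Variants without a row are treated as untested (`unknown`).
#' @param xlr_genes,female_specific_genes gene-specific X-linked rule lists.
#' @param hgmd optional data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `stratum`) assigning reported-phenotype strata by exact allele match;
#'   strata are `non_disease_phenotype`, `disease_phenotype`,
#'   `unknown_or_uncertain`. Unmatched pURVs get `not_registered`.
#' @return data.frame with one row per non-excluded case: `id`,
#'   `carries_durv_in_known`, `purv` (logical), `purv_rule`, `purv_class`,
#'   `parental_mosaic`, `hgmd_stratum`.
#' @export
assign_purv_status <- function(cohort, known_genes, trio_calls = NULL,
                               xlr_genes = c("PIGA", "ARX", "IQSEC2",
                                             "ARHGEF9"),
                               female_specific_genes = "PCDH19",
                               hgmd = NULL) {
  stopifnot(inherits(cohort, "urv_cohort"))
  if (is.null(cohort$variants$class)) {
    stop("run classify_variants() first", call. = FALSE)
  }
  if (is.null(known_genes) || !length(known_genes)) {
    stop("known_genes must be a non-empty gene set", call. = FALSE)
  }
  v <- cohort$variants
  keep <- which(v$class %in% expand_class("durv") & v$gene %in% known_genes)
  if (!is.null(v$rarity)) keep <- keep[v$rarity[keep] == "singleton"]
  ct <- carrier_table(cohort)
  ct <- ct[ct$variant %in% keep, , drop = FALSE]
  cases <- included_ids(cohort, "case")
  ct <- ct[ct$id %in% cases, , drop = FALSE]

  vkey <- function(chrom, pos, ref, alt, id = NULL) {
    base <- paste(normalize_chrom(chrom), as.integer(pos), ref, alt,
                  sep = ":")
    if (is.null(id)) base else paste(id, base, sep = "@")
  }
  inheritance <- rep("unknown", nrow(ct))
  if (!is.null(trio_calls) && nrow(trio_calls)) {
    tk <- vkey(trio_calls$chrom, trio_calls$pos, trio_calls$ref,
               trio_calls$alt, trio_calls$id)
    ck <- vkey(v$chrom[ct$variant], v$pos[ct$variant], v$ref[ct$variant],
               v$alt[ct$variant], ct$id)
    hit <- match(ck, tk)
    inheritance[!is.na(hit)] <- trio_calls$inheritance[hit[!is.na(hit)]]
  }

  site <- classify_site(v$chrom[ct$variant], v$pos[ct$variant])
  gene <- v$gene[ct$variant]
  gt <- ct$genotype
  de_novo_like <- inheritance %in% c("de_novo", "mosaic_parent")
  on_x <- site %in% c("X_nonPAR")
  autosomal <- site %in% c("autosome", "PAR")

  rule <- rep(NA_character_, nrow(ct))
  rule[autosomal & de_novo_like] <- "autosomal_de_novo"
  r2 <- is.na(rule) & gene %in% xlr_genes & on_x &
    gt %in% c("hom", "hemi") & inheritance %in% c("maternal", "de_novo",
                                                  "mosaic_parent")
  rule[r2] <- "xlr_hemizygous"
  r3 <- is.na(rule) & gene %in% female_specific_genes & on_x & gt == "het" &
    inheritance %in% c("paternal", "de_novo", "mosaic_parent")
  rule[r3] <- "pcdh19_het"
  r4 <- is.na(rule) & on_x & !gene %in% c(xlr_genes, female_specific_genes) &
    de_novo_like
  rule[r4] <- "x_de_novo"

  ct$rule <- rule
  ct$class <- as.character(v$class[ct$variant])
  ct$parental_mosaic <- inheritance == "mosaic_parent"
  ct$pos <- v$pos[ct$variant]
  ct$key <- vkey(v$chrom[ct$variant], ct$pos, v$ref[ct$variant],
                 v$alt[ct$variant])

  stratum_of <- function(key) {
    if (is.null(hgmd) || !nrow(hgmd)) return("not_registered")
    hk <- vkey(hgmd$chrom, hgmd$pos, hgmd$ref, hgmd$alt)
    i <- match(key, hk)
    if (is.na(i)) "not_registered" else as.character(hgmd$stratum[i])
  }

  out <- do.call(rbind, lapply(cases, function(case_id) {
    rows <- ct[ct$id == case_id, , drop = FALSE]
    carrier <- nrow(rows) > 0L
    qual <- rows[!is.na(rows$rule), , drop = FALSE]
    if (nrow(qual)) {
      qual <- qual[order(qual$pos), , drop = FALSE]  # deterministic pick
      data.frame(id = case_id, carries_durv_in_known = TRUE, purv = TRUE,
                 purv_rule = qual$rule[1], purv_class = qual$class[1],
                 parental_mosaic = qual$parental_mosaic[1],
                 hgmd_stratum = stratum_of(qual$key[1]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = case_id, carries_durv_in_known = carrier, purv = FALSE,
                 purv_rule = NA_character_, purv_class = NA_character_,
                 parental_mosaic = FALSE, hgmd_stratum = NA_character_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Build the nested case subsets
#'
#' From per-case pURV statuses, constructs the named case subsets used by
#' the stratified burden analyses. The subsets nest: pURV carriers are a
#' subset of known-gene dURV carriers, which are a subset of all cases; the
#' pURV carriers are partitioned by pURV class (null vs consensus-damaging
#' missense) and by reported-phenotype stratum, where `not_registered`
#' variants are pooled with `unknown_or_uncertain`.
#'
#' @param statuses data.frame from [assign_purv_status()].
#' @return named list of case-id character vectors: `all_cases`,
#'   `no_known_durv`, `known_durv_carriers`, `purv_carriers`, `purv_null`,
#'   `purv_cd_missense`, `purv_hgmd_non_disease`, `purv_hgmd_disease`,
#'   `purv_hgmd_unknown`.
#' @export
make_case_subsets <- function(statuses) {
  purv <- statuses[statuses$purv, , drop = FALSE]
  list(
    all_cases = statuses$id,
    no_known_durv = statuses$id[!statuses$carries_durv_in_known],
    known_durv_carriers = statuses$id[statuses$carries_durv_in_known],
    purv_carriers = purv$id,
    purv_null = purv$id[purv$purv_class == "null"],
    purv_cd_missense = purv$id[purv$purv_class == "cd_missense"],
    purv_hgmd_non_disease = purv$id[purv$hgmd_stratum ==
                                      "non_disease_phenotype"],
    purv_hgmd_disease = purv$id[purv$hgmd_stratum == "disease_phenotype"],
    purv_hgmd_unknown = purv$id[purv$hgmd_stratum %in%
                                  c("unknown_or_uncertain",
                                    "not_registered")]
  )
}
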