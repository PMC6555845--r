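# Controlled consequence vocabulary (SnpEff-style sequence-ontology labels).
.null_effects <- c("stop_gained", "frameshift_variant",
                   "splice_acceptor_variant", "splice_donor_variant",
                   "stop_lost")
.reclassified_high <- c("protein_protein_contact", "start_lost")
.moderate_effects <- c("missense_variant", "inframe_insertion",
                       "inframe_deletion", "disruptive_inframe_insertion",
                       "disruptive_inframe_deletion")
.synonymous_effects <- c("synonymous_variant", "stop_retained_variant",
                         "start_retained_variant")
.noncoding_effects <- c("intron_variant", "intergenic_region",
                        "5_prime_UTR_variant", "3_prime_UTR_variant",
                        "upstream_gene_variant", "downstream_gene_variant",
                        "non_coding_transcript_exon_variant",
                        "splice_region_variant")

.leaf_classes <- c("null", "cd_missense", "other_moderate",
                   "fcdhs_synonymous", "sr_synonymous", "other_synonymous",
                   "noncoding")

#' Expand a functional class label to its leaf classes
#'
#' The taxonomy has seven mutually exclusive leaves plus aggregate labels:
#' `moderate` (= `cd_missense` + `other_moderate`), `synonymous` (its three
#' leaves), `durv` (damaging URVs: `null` + `cd_missense`) and `coding`
#' (everything but `noncoding`).
#'
#' @param label a leaf or aggregate class label.
#' @return character vector of leaf class labels.
#' @export
expand_class <- function(label) {
  switch(label,
    moderate = c("cd_missense", "other_moderate"),
    synonymous = c("fcdhs_synonymous", "sr_synonymous", "other_synonymous"),
    durv = c("null", "cd_missense"),
    coding = setdiff(.leaf_classes, "noncoding"),
    all = .leaf_classes,
    {
      if (!label %in% .leaf_classes) {
        stop("unknown functional class: ", label, call. = FALSE)
      }
      label
    }
  )
}

#' Classify variants into the functional taxonomy
#'
#' Assigns each variant one of seven mutually exclusive leaf classes:
#' \describe{
#'   \item{null}{HIGH-impact loss-of-function consequences (nonsense,
#'     frameshift, splice donor/acceptor, read-through), except
#'     protein-protein-contact and start-lost variants, which are
#'     reclassified into the Moderate group.}
#'   \item{cd_missense}{Moderate-impact variants called damaging (`D`) by
#'     all seven in-silico predictors (SIFT, PolyPhen-2 HumVar and HumDiv,
#'     LRT, MutationTaster, MutationAssessor, PROVEAN). An `NA` in any
#'     predictor disqualifies: consensus requires seven affirmative calls,
#'     so inframe indels (usually unscored) land in `other_moderate`.}
#'   \item{other_moderate}{the remaining Moderate-impact variants.}
#'   \item{sr_synonymous}{synonymous variants flagged as splice-region
#'     (within the last/first 3 bp of an exon adjacent to an intron).}
#'   \item{fcdhs_synonymous}{synonymous variants inside the supplied DNase I
#'     hypersensitive site index (frontal cortex).}
#'   \item{other_synonymous}{remaining synonymous variants.}
#'   \item{noncoding}{MODIFIER-impact and other non-coding consequences.}
#' }
#'
#' A synonymous variant can satisfy both the splice-region and the DHS
#' rule; `synonymous_precedence` selects which subclass wins so that the
#' leaves stay a partition (default: splice-region).
#'
#' @param cohort an `urv_cohort`.
#' @param dhs optional `GRanges` of DNase I hypersensitive sites (from
#'   [read_intervals()]). Without it no variant is `fcdhs_synonymous`.
#' @param synonymous_precedence `"sr"` (default) or `"fcdhs"`.
#' @return the cohort with a `class` factor column added to the variant
#'   table.
#' @export
classify_variants <- function(cohort, dhs = NULL,
                              synonymous_precedence = c("sr", "fcdhs")) {
  stopifnot(inherits(cohort, "urv_cohort"))
  synonymous_precedence <- match.arg(synonymous_precedence)
  v <- cohort$variants
  known <- c(.null_effects, .reclassified_high, .moderate_effects,
             .synonymous_effects, .noncoding_effects)
  unknown <- setdiff(unique(v$effect), known)
  if (length(unknown)) {
    stop("unknown consequence label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  preds <- as.matrix(v[.prediction_cols])
  all_damaging <- rowSums(preds == "D", na.rm = TRUE) == 7L

  cls <- rep(NA_character_, nrow(v))
  is_high <- v$impact == "HIGH" & !v$effect %in% .reclassified_high
  is_moderate <- (v$impact == "MODERATE" | v$effect %in% .reclassified_high) &
    !is_high & !v$effect %in% c(.synonymous_effects, .noncoding_effects)
  is_syn <- v$effect %in% .synonymous_effects
  cls[is_high] <- "null"
  cls[is_moderate & all_damaging] <- "cd_missense"
  cls[is_moderate & !all_damaging] <- "other_moderate"

  if (any(is_syn)) {
    in_dhs <- rep(FALSE, nrow(v))
    if (!is.null(dhs)) {
      in_dhs[is_syn] <- point_in_intervals(dhs, v$chrom[is_syn],
                                           v$pos[is_syn])
    }
    sr <- v$splice_region
    if (synonymous_precedence == "sr") {
      cls[is_syn & sr] <- "sr_synonymous"
      cls[is_syn & !sr & in_dhs] <- "fcdhs_synonymous"
      cls[is_syn & !sr & !in_dhs] <- "other_synonymous"
    } else {
      cls[is_syn & in_dhs] <- "fcdhs_synonymous"
      cls[is_syn & !in_dhs & sr] <- "sr_synonymous"
      cls[is_syn & !in_dhs & !sr] <- "other_synonymous"
    }
  }
  cls[is.na(cls)] <- "noncoding"
  cohort$variants$class <- factor(cls, levels = .leaf_classes)
  cohort
}

#' Splice-region synonymous rule
#'
#' A position is splice-region synonymous when it lies within the last or
#' first 3 bp of an exon that abuts an intron. The first exon's start and
#' the last exon's end border no intron, so positions there do not qualify;
#' in particular nothing qualifies in a single-exon transcript.
#'
#' @param pos 1-based position(s).
#' @param exons data.frame with 1-based closed `start`/`end` columns, one
#'   row per exon of the transcript (any order).
#' @return logical vector.
#' @export
is_sr_synonymous <- function(pos, exons) {
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  n_ex <- nrow(exons)
  vapply(pos, function(p) {
    i <- which(p >= exons$start & p <= exons$end)
    if (!length(i)) {
      stop("position ", p, " lies outside every exon of the model",
           call. = FALSE)
    }
    i <- i[1]
    near_start <- p - exons$start[i] < 3L   # first 3 bp of the exon
    near_end <- exons$end[i] - p < 3L       # last 3 bp of the exon
    (near_start && i > 1L) || (near_end && i < n_ex)
  }, NA)
}
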