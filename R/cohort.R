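# Column contracts for the three flat tables a cohort is built from.
.variant_cols <- c(
  "chrom", "pos", "ref", "alt", "gene", "effect", "impact",
  "sift", "pph2_var", "pph2_div", "lrt", "mutation_taster",
  "mutation_assessor", "provean", "splice_region",
  "in_exac", "in_esp", "in_tommo", "carriers"
)
.prediction_cols <- c("sift", "pph2_var", "pph2_div", "lrt",
                      "mutation_taster", "mutation_assessor", "provean")
.sample_cols <- c("id", "status", "sex", "karyotype", "callable_fraction",
                  paste0("pc", 1:10))
.gene_cols <- c("gene", "pli", "mu_nonsense", "mu_frameshift", "mu_splice",
                "mu_missense", "mu_synonymous")

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that `"chr1"` and `"1"` refer to the
#' same sequence throughout the package (done once at ingestion).
#'
#' @param chrom character vector of chromosome names.
#' @return character vector without the `"chr"` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Vectorized expansion of "id1:het,id2:hom" carrier strings into a long
# table with one row per (variant, carrier) pair.
.carrier_long <- function(carriers) {
  sp <- strsplit(as.character(carriers), ",", fixed = TRUE)
  n <- lengths(sp)
  flat <- unlist(sp, use.names = FALSE)
  if (length(flat) && any(!grepl(":", flat, fixed = TRUE))) {
    stop("malformed carrier entry (expected id:genotype): ",
         flat[!grepl(":", flat, fixed = TRUE)][1], call. = FALSE)
  }
  data.frame(
    variant = rep.int(seq_along(sp), n),
    id = sub(":[^:]*$", "", flat),
    genotype = sub("^.*:", "", flat),
    stringsAsFactors = FALSE
  )
}

# allele contribution of one carrier call: het 1; hom 2 on diploid sites;
# hemizygous calls (hemi, or hom on male X-nonPAR/Y) count once
.allele_contribution <- function(genotype, site_class = "autosome") {
  ifelse(genotype == "het", 1L,
         ifelse(genotype == "hemi", 1L,
                ifelse(site_class %in% c("X_nonPAR", "Y"), 1L, 2L)))
}

#' Construct a cohort object
#'
#' Bundles a variant table, a sample manifest and per-gene metadata into a
#' validated `urv_cohort`. Carrier strings are parsed once (and cached) and
#' the cohort allele count recomputed from them. Variants whose gene has no
#' entry in `genes` are kept but their ids are collected in the
#' `"unannotated"` attribute.
#'
#' @param variants data.frame with the variant-table columns (see
#'   [read_cohort()] for the schema).
#' @param samples data.frame sample manifest (`id`, `status`, `sex`,
#'   `karyotype`, `callable_fraction`, `pc1`..`pc10`).
#' @param genes data.frame of per-gene pLI and per-consequence haploid de
#'   novo mutation rates.
#' @return an object of class `urv_cohort`: a list with elements
#'   `variants`, `samples`, `genes`. The variant table gains an integer
#'   `cohort_allele_count`; the sample table gains logical `excluded` (all
#'   `FALSE` until QC runs).
#' @export
urv_cohort <- function(variants, samples, genes) {
  missing_v <- setdiff(.variant_cols, names(variants))
  if (length(missing_v)) {
    stop("variant table is missing mandatory column(s): ",
         paste(missing_v, collapse = ", "), call. = FALSE)
  }
  missing_s <- setdiff(.sample_cols, names(samples))
  if (length(missing_s)) {
    stop("sample manifest is missing mandatory column(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  missing_g <- setdiff(.gene_cols, names(genes))
  if (length(missing_g)) {
    stop("gene table is missing mandatory column(s): ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)

  if (anyDuplicated(samples$id)) {
    stop("duplicated sample id(s) in manifest", call. = FALSE)
  }
  if (!all(samples$status %in% c("case", "control"))) {
    stop("sample status must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(samples$sex %in% c("male", "female"))) {
    stop("sample sex must be 'male' or 'female'", call. = FALSE)
  }
  if (!all(samples$karyotype %in% c("normal", "XXY"))) {
    stop("sample karyotype must be 'normal' or 'XXY'", call. = FALSE)
  }
  cf <- samples$callable_fraction
  if (any(!is.finite(cf) | cf < 0 | cf > 1)) {
    stop("callable_fraction must lie in [0, 1]", call. = FALSE)
  }

  ct <- NULL
  if (nrow(variants)) {
    if (any(grepl(",", variants$alt, fixed = TRUE))) {
      stop("multi-allelic rows must be pre-split to one row per alt allele",
           call. = FALSE)
    }
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
      stop("ref/alt alleles must be non-empty strings", call. = FALSE)
    }
    if (any(!is.finite(variants$pos) | variants$pos < 1)) {
      stop("variant pos must be >= 1", call. = FALSE)
    }
    variants$chrom <- normalize_chrom(variants$chrom)
    variants$pos <- as.integer(variants$pos)
    for (col in .prediction_cols) {
      v <- as.character(variants[[col]])
      v[v %in% c("NA", "", ".")] <- NA_character_
      if (!all(v %in% c("D", "T") | is.na(v))) {
        stop("prediction column '", col, "' must be D, T or NA", call. = FALSE)
      }
      variants[[col]] <- v
    }
    variants$splice_region <- as.integer(variants$splice_region) == 1L
    for (col in c("in_exac", "in_esp", "in_tommo")) {
      variants[[col]] <- as.integer(variants[[col]]) == 1L
    }
    if (any(!nzchar(variants$carriers) | is.na(variants$carriers))) {
      stop("every variant must have at least one carrier", call. = FALSE)
    }
    ct <- .carrier_long(variants$carriers)
    unknown <- setdiff(unique(ct$id), samples$id)
    if (length(unknown)) {
      stop("carrier id(s) absent from sample manifest: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!all(ct$genotype %in% c("het", "hom", "hemi"))) {
      stop("carrier genotypes must be het, hom or hemi", call. = FALSE)
    }
    site <- classify_site(variants$chrom, variants$pos)
    contrib <- .allele_contribution(ct$genotype, site[ct$variant])
    ac <- integer(nrow(variants))
    agg <- rowsum(as.integer(contrib), ct$variant)
    ac[as.integer(rownames(agg))] <- agg[, 1]
    variants$cohort_allele_count <- ac
  } else {
    variants$cohort_allele_count <- integer(0)
    ct <- data.frame(variant = integer(0), id = character(0),
                     genotype = character(0))
  }

  if (any(genes$pli < 0 | genes$pli > 1, na.rm = TRUE)) {
    stop("pLI must lie in [0, 1]", call. = FALSE)
  }
  mu_cols <- grep("^mu_", .gene_cols, value = TRUE)
  if (any(as.matrix(genes[mu_cols]) < 0, na.rm = TRUE)) {
    stop("per-gene mutation rates must be nonnegative", call. = FALSE)
  }

  unannotated <- setdiff(unique(variants$gene), genes$gene)
  samples$excluded <- FALSE
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  obj <- structure(list(variants = variants, samples = samples, genes = genes),
                   class = "urv_cohort")
  attr(obj, "unannotated") <- unannotated
  # parsed carriers cached; safe because downstream steps only add columns
  attr(obj, "carrier_cache") <- ct
  obj
}

#' Read a cohort from flat tables
#'
#' Reads the tab-separated variant table, sample manifest and gene metadata
#' and assembles a validated [urv_cohort()]. The variant table is a
#' transcript-collapsed flattening of an annotated VCF: one row per alt
#' allele, with SnpEff-style consequence/impact, the seven in-silico missense
#' predictions (`D`/`T`/`NA`), the splice-region flag, external-panel
#' presence flags and a comma-separated `id:genotype` carrier field.
#'
#' @param variant_table_path,sample_manifest_path,gene_info_path paths to the
#'   three TSV files (header required).
#' @return an `urv_cohort`.
#' @export
read_cohort <- function(variant_table_path, sample_manifest_path,
                        gene_info_path) {
  read_tsv <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE)
  }
  variants <- read_tsv(variant_table_path)
  variants$chrom <- as.character(variants$chrom)
  samples <- read_tsv(sample_manifest_path)
  samples$id <- as.character(samples$id)
  genes <- read_tsv(gene_info_path)
  urv_cohort(variants, samples, genes)
}

#' Write a cohort back to flat tables
#'
#' Inverse of [read_cohort()]: emits `variants.tsv`, `samples.tsv` and
#' `genes.tsv` under `dir` in the exact input schema, so that a written
#' cohort re-reads field-by-field identical.
#'
#' @param cohort an `urv_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "urv_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  for (col in .prediction_cols) {
    x <- v[[col]]
    x[is.na(x)] <- "NA"
    v[[col]] <- x
  }
  v$splice_region <- as.integer(v$splice_region)
  for (col in c("in_exac", "in_esp", "in_tommo")) v[[col]] <- as.integer(v[[col]])
  paths <- file.path(dir, c("variants.tsv", "samples.tsv", "genes.tsv"))
  utils::write.table(v[.variant_cols], paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$samples[.sample_cols], paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$genes[.gene_cols], paths[3], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a gene set (one gene id per line)
#'
#' @param path text file, one gene id per line; blank lines ignored.
#' @param name optional set name (defaults to the file name).
#' @return character vector of unique gene ids with attribute `"name"`.
#' @export
read_gene_set <- function(path, name = basename(path)) {
  genes <- trimws(readLines(path, warn = FALSE))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "' contains duplicates; de-duplicated")
    genes <- unique(genes)
  }
  attr(genes, "name") <- name
  genes
}

#' Long-format carrier table
#'
#' One row per (variant, carrier) pair, parsed from the carrier strings
#' (cached at construction).
#'
#' @param cohort an `urv_cohort`.
#' @return data.frame with columns `variant` (row index into
#'   `cohort$variants`), `id` and `genotype`.
#' @export
carrier_table <- function(cohort) {
  stopifnot(inherits(cohort, "urv_cohort"))
  ct <- attr(cohort, "carrier_cache")
  if (is.null(ct)) ct <- .carrier_long(cohort$variants$carriers)
  ct
}

#' @export
print.urv_cohort <- function(x, ...) {
  s <- x$samples
  cat("urv_cohort:", nrow(x$variants), "variants,",
      nrow(s), "individuals (", sum(s$status == "case"), "cases /",
      sum(s$status == "control"), "controls ),",
      nrow(x$genes), "genes\n")
  if (any(s$excluded)) {
    cat("  ", sum(s$excluded), "individuals excluded by QC\n")
  }
  if (!is.null(x$variants$rarity)) {
    tab <- table(x$variants$rarity)
    cat("  rarity:", paste(names(tab), tab, collapse = ", "), "\n")
  }
  if (!is.null(x$variants$class)) {
    tab <- table(x$variants$class)
    cat("  classes:", paste(names(tab), tab, collapse = ", "), "\n")
  }
  un <- attr(x, "unannotated")
  if (length(un)) cat("  ", length(un), "gene id(s) without metadata\n")
  invisible(x)
}

# ids of individuals retained for analysis
included_ids <- function(cohort, status = NULL) {
  s <- cohort$samples
  keep <- !s$excluded
  if (!is.null(status)) keep <- keep & s$status %in% status
  s$id[keep]
}
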