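#' Read genomic intervals from a BED file
#'
#' Reads BED3+ intervals (0-based half-open, the BED convention) and converts
#' them once, at ingestion, to the 1-based closed convention used for variant
#' positions, returning a `GRanges` index suitable for point-membership
#' queries via [point_in_intervals()].
#'
#' @param bed_path path to a BED file (at least chrom/start/end columns; no
#'   header). Track/browser lines are skipped.
#' @return a [GenomicRanges::GRanges] with normalized (chr-prefix-stripped)
#'   seqnames.
#' @export
read_intervals <- function(bed_path) {
  lines <- readLines(bed_path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L)) {
    stop("BED format error: fewer than 3 fields on line ",
         which(lengths(fields) < 3L)[1], call. = FALSE)
  }
  chrom <- normalize_chrom(vapply(fields, `[`, "", 1L))
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (any(is.na(start0) | is.na(end0))) {
    stop("BED format error: non-numeric start/end", call. = FALSE)
  }
  if (any(start0 >= end0)) {
    stop("BED format error: start >= end on line ",
         which(start0 >= end0)[1], call. = FALSE)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L,
                                                 end = end0))
}

#' Point membership in an interval index
#'
#' @param index a `GRanges` index, e.g. from [read_intervals()].
#' @param chrom,pos parallel vectors of chromosome names and 1-based
#'   positions.
#' @return logical vector: is each point inside at least one interval?
#' @export
point_in_intervals <- function(index, chrom, pos) {
  if (length(chrom) == 1L && length(pos) > 1L) chrom <- rep(chrom, length(pos))
  stopifnot(length(chrom) == length(pos))
  if (!length(pos)) return(logical(0))
  query <- GenomicRanges::GRanges(normalize_chrom(chrom),
                                  IRanges::IRanges(pos, pos))
  # seqlevels of query and index may legitimately differ; that is not a
  # mismatch worth surfacing for a membership query
  suppressWarnings(GenomicRanges::countOverlaps(query, index) > 0L)
}
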