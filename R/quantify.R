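#' Count reads per feature across samples
#'
#' A read increments a feature when it overlaps the feature by at least
#' `min_overlap_frac` of the read length and its transcript strand matches
#' the feature strand. Ambiguous reads are excluded. A read overlapping two
#' features that both qualify increments both.
#'
#' @param features `GRanges` of stranded features (assembled models or sense
#'   genes), named by their identifier.
#' @param samples Named list of classified-read `GRanges`
#'   (from [classify_reads()]); names become column names.
#' @param min_overlap_frac Minimum overlap as a fraction of read length.
#' @return Integer matrix, features x samples, with feature identifiers as
#'   rownames.
#' @export
count_reads <- function(features, samples, min_overlap_frac = 0.5) {
  stopifnot(is.list(samples), !is.null(names(samples)))
  ids <- if (!is.null(names(features))) names(features) else
    as.character(seq_along(features))
  counts <- vapply(samples, function(reads) {
    reads <- reads[reads$category != "ambiguous"]
    if (length(reads) == 0) return(integer(length(features)))
    hits <- GenomicRanges::findOverlaps(reads, features, ignore.strand = FALSE)
    ov <- BiocGenerics::width(IRanges::pintersect(
      IRanges::ranges(reads)[S4Vectors::queryHits(hits)],
      IRanges::ranges(features)[S4Vectors::subjectHits(hits)]))
    qual <- ov >= min_overlap_frac *
      BiocGenerics::width(reads)[S4Vectors::queryHits(hits)]
    tabulate(S4Vectors::subjectHits(hits)[qual], nbins = length(features))
  }, integer(length(features)))
  counts <- matrix(counts, nrow = length(features),
                   dimnames = list(ids, names(samples)))
  storage.mode(counts) <- "integer"
  counts
}

#' Library sizes of classified samples
#'
#' Per-sample totals of mapped, filtered, non-ambiguous reads — the
#' normalisation denominator used throughout.
#'
#' @param samples Named list of classified-read `GRanges`.
#' @return Named numeric vector.
#' @export
lib_sizes <- function(samples) {
  vapply(samples, function(r) sum(r$category != "ambiguous"), numeric(1))
}

#' Counts per million
#'
#' @param counts Count matrix (features x samples).
#' @param lib Per-sample library sizes; defaults to the column sums.
#' @return Numeric matrix of CPM values.
#' @export
cpm_matrix <- function(counts, lib = colSums(counts)) {
  if (any(lib <= 0)) stop("library size must be positive for all samples")
  t(t(counts) / lib) * 1e6
}
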