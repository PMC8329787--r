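#' Load a gene annotation
#'
#' Reads gene-level features from a GFF3, GTF or BED file into a
#' \link[GenomicRanges]{GRanges} with a `gene_id` metadata column. GFF3/GTF
#' records are filtered to gene-level rows (`type` in `feature_type`); BED
#' files are consumed whole, with the name column as `gene_id`. All
#' coordinate-convention handling (BED 0-based half-open vs GFF 1-based
#' inclusive) is performed by \pkg{rtracklayer}; internally everything is a
#' GRanges (1-based, closed intervals).
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"`, `"gff3"`, `"gtf"`, `"bed"`. `"auto"` guesses
#'   from the file extension.
#' @param feature_type For GFF3/GTF, the `type` values retained as genes.
#' @param chrom_sizes Optional named vector of chromosome lengths; when given,
#'   features are validated to lie inside their chromosome and the lengths are
#'   stored in the object's `seqinfo`.
#' @return A `GRanges`, sorted by position, named by `gene_id`, with metadata
#'   columns `gene_id` and `biotype`.
#' @export
load_annotation <- function(path, format = c("auto", "gff3", "gtf", "bed"),
                            feature_type = "gene", chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
      gff = "gff3", gff3 = "gff3", gtf = "gtf", bed = "bed",
      stop("cannot guess annotation format from extension '", ext, "'"))
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else format)
  if (format %in% c("gff3", "gtf")) {
    if ("type" %in% names(S4Vectors::mcols(gr))) {
      gr <- gr[as.character(gr$type) %in% feature_type]
    }
    id <- NULL
    for (col in c("gene_id", "ID", "Name", "locus_tag")) {
      if (col %in% names(S4Vectors::mcols(gr))) {
        cand <- as.character(S4Vectors::mcols(gr)[[col]])
        if (!all(is.na(cand))) { id <- cand; break }
      }
    }
    if (is.null(id) && length(gr) > 0)
      stop("no gene identifier attribute (gene_id/ID/Name) found in ", path)
    biotype <- if ("biotype" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$biotype) else rep("gene", length(gr))
  } else {
    id <- if ("name" %in% names(S4Vectors::mcols(gr)))
      as.character(gr$name) else character(length(gr))
    biotype <- rep("gene", length(gr))
  }
  if (length(gr) == 0) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$gene_id <- character(0)
    S4Vectors::mcols(out)$biotype <- character(0)
    return(out)
  }
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                IRanges::ranges(gr),
                                strand = BiocGenerics::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(gene_id = id, biotype = biotype)
  validate_annotation(out, chrom_sizes = chrom_sizes)
}

#' Validate and finalize an annotation GRanges
#'
#' Checks strand, identifier uniqueness and (when sizes are known) that every
#' feature fits inside its chromosome; sorts by position and names the ranges
#' by `gene_id`.
#'
#' @param gr A `GRanges` with a `gene_id` metadata column.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @return The validated, sorted `GRanges`.
#' @export
validate_annotation <- function(gr, chrom_sizes = NULL) {
  if (length(gr) == 0) return(gr)
  id <- gr$gene_id
  if (any(is.na(id) | id == ""))
    stop("annotation has features with empty gene_id")
  if (anyDuplicated(id))
    stop("duplicate gene_id in annotation: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  str <- as.character(BiocGenerics::strand(gr))
  if (any(!str %in% c("+", "-")))
    stop("annotation features must be stranded (+ or -); found: ",
         paste(unique(str[!str %in% c("+", "-")]), collapse = ", "))
  if (!is.null(chrom_sizes)) {
    too_far <- BiocGenerics::end(gr) >
      chrom_sizes[as.character(GenomeInfoDb::seqnames(gr))]
    if (any(too_far, na.rm = TRUE))
      stop("feature(s) extend beyond chromosome end: ",
           paste(id[which(too_far)], collapse = ", "))
    GenomeInfoDb::seqlengths(gr) <-
      chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  }
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  names(gr) <- gr$gene_id
  gr
}

#' Query features overlapping an interval
#'
#' Returns exactly the annotation features with a nonzero overlap with the
#' 1-based closed interval `[start, end]` on `chrom`, in deterministic order
#' (start, then `gene_id`). An unknown chromosome yields an empty result.
#'
#' @param annotation A `GRanges` from [load_annotation()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval bounds; `end >= start`.
#' @return A `GRanges` subset of `annotation`.
#' @export
query_overlaps <- function(annotation, chrom, start, end) {
  stopifnot(end >= start, start >= 1)
  if (!chrom %in% GenomeInfoDb::seqlevels(annotation))
    return(annotation[integer(0)])
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, annotation, ignore.strand = TRUE)
  res <- annotation[S4Vectors::subjectHits(hits)]
  res[order(BiocGenerics::start(res), res$gene_id)]
}

#' Write an annotation (or any stranded feature set) as BED6
#'
#' @param gr A `GRanges`; the name column written is `gene_id` if present,
#'   else `feature_id`, else the range names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  out <- gr
  nm <- if ("gene_id" %in% names(S4Vectors::mcols(gr))) gr$gene_id
        else if ("feature_id" %in% names(S4Vectors::mcols(gr))) gr$feature_id
        else names(gr)
  S4Vectors::mcols(out) <- NULL
  out$name <- if (is.null(nm)) rep(".", length(gr)) else nm
  out$score <- rep(0L, length(gr))
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}
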