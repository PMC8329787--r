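#' Build a transcription-unit identifier
#'
#' Identifiers are `"<chrom>_<start>_<end>"` with 1-based inclusive
#' coordinates, the naming used for assembled antisense units (e.g.
#' `chrIII_268287_269650`).
#'
#' @param chrom Chromosome name(s).
#' @param start,end 1-based inclusive coordinates; `end >= start`.
#' @return Character vector of identifiers.
#' @export
make_feature_id <- function(chrom, start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  paste(chrom, start, end, sep = "_")
}

#' Parse a transcription-unit identifier back to coordinates
#'
#' Inverse of [make_feature_id()]; chromosome names may themselves contain
#' underscores (the last two underscore-separated fields are coordinates).
#'
#' @param id Character vector of identifiers.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
parse_feature_id <- function(id) {
  m <- regmatches(id, regexec("^(.+)_([0-9]+)_([0-9]+)$", id))
  bad <- lengths(m) != 4
  if (any(bad)) stop("malformed feature id: ", paste(id[bad], collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Assemble antisense/intergenic reads into transcription units
#'
#' Reference-free assembly by strand-aware interval merging: antisense and
#' intergenic reads are pooled, and per (chromosome, transcript strand) reads
#' whose gap is at most `max_gap` are merged into maximal clusters. Clusters
#' supported by at least `min_reads` reads and spanning at least `min_length`
#' bp become transcript models; a model's origin is `antisense` when any
#' member read is antisense, else `intergenic`.
#'
#' @param classified `GRanges` from [classify_reads()]; only reads with
#'   category `antisense` or `intergenic` are used (ambiguous and sense reads
#'   are ignored).
#' @param max_gap Maximum gap (bp) bridged when merging (default 50).
#' @param min_reads Minimum supporting reads per model (default 3).
#' @param min_length Minimum model span in bp (default 100).
#' @return A `GRanges` of models named by `feature_id`, with metadata columns
#'   `feature_id`, `n_support_reads`, `origin`.
#' @export
assemble_transcripts <- function(classified, max_gap = 50, min_reads = 3,
                                 min_length = 100) {
  reads <- classified[classified$category %in% c("antisense", "intergenic")]
  if (length(reads) == 0) return(empty_models())
  clusters <- GenomicRanges::reduce(reads, min.gapwidth = max_gap + 1L,
                                    ignore.strand = FALSE)
  hits <- GenomicRanges::findOverlaps(reads, clusters, ignore.strand = FALSE)
  cl <- S4Vectors::subjectHits(hits)
  n_support <- tabulate(cl, nbins = length(clusters))
  is_anti <- reads$category[S4Vectors::queryHits(hits)] == "antisense"
  any_anti <- tabulate(cl[is_anti], nbins = length(clusters)) > 0
  keep <- n_support >= min_reads & BiocGenerics::width(clusters) >= min_length
  models <- clusters[keep]
  if (length(models) == 0) return(empty_models())
  S4Vectors::mcols(models) <- S4Vectors::DataFrame(
    feature_id = make_feature_id(as.character(GenomeInfoDb::seqnames(models)),
                                 BiocGenerics::start(models),
                                 BiocGenerics::end(models)),
    n_support_reads = n_support[keep],
    origin = ifelse(any_anti[keep], "antisense", "intergenic"))
  models <- GenomicRanges::sort(models, ignore.strand = TRUE)
  names(models) <- models$feature_id
  models
}

empty_models <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = character(0), n_support_reads = integer(0),
    origin = character(0))
  gr
}

#' Associate antisense units with their overlapping sense genes
#'
#' Emits one pair for every (model, gene) combination with at least 1 bp of
#' overlap where the gene lies on the strand opposite to the model. Purely
#' intergenic models (no opposite-strand gene overlap) yield no pairs. A gene
#' linked by at least one pair is an antisense-transcript-enriched (ATE)
#' gene; one gene may pair with several units and vice versa.
#'
#' @param models `GRanges` from [assemble_transcripts()].
#' @param annotation Gene `GRanges`.
#' @return A data.frame with columns `feature_id`, `gene_id`, `overlap_bp`,
#'   ordered by model position then gene id.
#' @export
associate_antisense_with_genes <- function(models, annotation) {
  empty <- data.frame(feature_id = character(0), gene_id = character(0),
                      overlap_bp = integer(0), stringsAsFactors = FALSE)
  if (length(models) == 0 || length(annotation) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(models, annotation, ignore.strand = TRUE)
  opp <- as.character(BiocGenerics::strand(models))[S4Vectors::queryHits(hits)] !=
    as.character(BiocGenerics::strand(annotation))[S4Vectors::subjectHits(hits)]
  hits <- hits[opp]
  if (length(hits) == 0) return(empty)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(models)[S4Vectors::queryHits(hits)],
    IRanges::ranges(annotation)[S4Vectors::subjectHits(hits)]))
  out <- data.frame(
    feature_id = models$feature_id[S4Vectors::queryHits(hits)],
    gene_id = annotation$gene_id[S4Vectors::subjectHits(hits)],
    overlap_bp = ov, stringsAsFactors = FALSE)
  out[order(match(out$feature_id, models$feature_id), out$gene_id), ,
      drop = FALSE]
}

#' Write transcript models as GTF
#'
#' One `transcript` line per model with `transcript_id` and `gene_id` set to
#' the model's `feature_id`.
#'
#' @param models `GRanges` from [assemble_transcripts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(models, path) {
  lines <- sprintf(
    "%s\tantisenseq\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    as.character(GenomeInfoDb::seqnames(models)),
    BiocGenerics::start(models), BiocGenerics::end(models),
    as.character(BiocGenerics::strand(models)),
    models$feature_id, models$feature_id)
  writeLines(lines, path)
  invisible(path)
}
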