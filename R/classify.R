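#' Library protocols
#'
#' Strand-specific RNA-seq protocols supported for transcript-strand
#' inference. Under the dUTP protocol (single-end), the sequenced read aligns
#' opposite to the originating transcript: `stranded_reverse`. Under
#' `stranded_forward` the read aligns on the transcript strand. `unstranded`
#' libraries carry no strand information and cannot support sense/antisense
#' calls.
#'
#' @export
LIBRARY_PROTOCOLS <- c("stranded_reverse", "stranded_forward", "unstranded")

READ_CATEGORIES <- c("sense", "antisense", "intergenic", "ambiguous")

#' Infer the transcript strand of an aligned read
#'
#' @param align_strand Character vector of alignment strands (`"+"`/`"-"`,
#'   from SAM FLAG bit 0x10).
#' @param protocol One of [LIBRARY_PROTOCOLS]. `stranded_reverse` (dUTP)
#'   flips the alignment strand; `stranded_forward` keeps it; `unstranded`
#'   is an error because strand calls are impossible.
#' @return Character vector of transcript strands.
#' @export
infer_transcript_strand <- function(align_strand,
                                    protocol = c("stranded_reverse",
                                                 "stranded_forward",
                                                 "unstranded")) {
  protocol <- match.arg(protocol)
  if (protocol == "unstranded")
    stop("transcript strand is undefined for an unstranded library")
  s <- as.character(align_strand)
  if (any(!s %in% c("+", "-")))
    stop("alignment strand must be '+' or '-'")
  if (protocol == "stranded_reverse") ifelse(s == "+", "-", "+") else s
}

#' Classify reads against a gene annotation
#'
#' Each mapped, filtered read gets a transcript strand (per `protocol`) and a
#' category. Genes overlapping the read by at least `min_overlap_frac` of the
#' read length qualify; with no qualifying gene the read is `intergenic`;
#' with qualifying genes all on the transcript strand it is `sense`; all on
#' the opposite strand, `antisense`; genes on both strands, `ambiguous`.
#'
#' @param reads `GRanges` of alignments (strand = alignment strand), e.g.
#'   from [read_alignments()].
#' @param annotation Gene `GRanges` from [load_annotation()].
#' @param protocol One of [LIBRARY_PROTOCOLS].
#' @param min_overlap_frac Minimum gene overlap as a fraction of read length
#'   (default 0.5).
#' @return A `GRanges` like `reads`, with strand replaced by the inferred
#'   transcript strand and metadata columns `category` (factor over
#'   sense/antisense/intergenic/ambiguous) and `gene_ids` (CharacterList of
#'   qualifying genes; empty for intergenic reads).
#' @export
classify_reads <- function(reads, annotation,
                           protocol = "stranded_reverse",
                           min_overlap_frac = 0.5) {
  tx_strand <- infer_transcript_strand(BiocGenerics::strand(reads), protocol)
  out <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(reads),
                                IRanges::ranges(reads),
                                strand = tx_strand)
  S4Vectors::mcols(out) <- S4Vectors::mcols(reads)

  hits <- GenomicRanges::findOverlaps(out, annotation, ignore.strand = TRUE)
  ov_w <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(out)[S4Vectors::queryHits(hits)],
    IRanges::ranges(annotation)[S4Vectors::subjectHits(hits)]))
  qual <- ov_w >= min_overlap_frac * BiocGenerics::width(out)[S4Vectors::queryHits(hits)]
  hits <- hits[qual]

  qh <- S4Vectors::queryHits(hits)
  gene_strand <- as.character(BiocGenerics::strand(annotation))[S4Vectors::subjectHits(hits)]
  same <- gene_strand == tx_strand[qh]
  n_same <- tabulate(qh[same], nbins = length(out))
  n_opp <- tabulate(qh[!same], nbins = length(out))

  category <- rep("intergenic", length(out))
  category[n_same > 0 & n_opp == 0] <- "sense"
  category[n_same == 0 & n_opp > 0] <- "antisense"
  category[n_same > 0 & n_opp > 0] <- "ambiguous"

  gl <- S4Vectors::split(annotation$gene_id[S4Vectors::subjectHits(hits)],
                         factor(qh, levels = seq_along(out)))
  S4Vectors::mcols(out)$category <- factor(category, levels = READ_CATEGORIES)
  S4Vectors::mcols(out)$gene_ids <- IRanges::CharacterList(gl)
  S4Vectors::metadata(out) <- S4Vectors::metadata(reads)
  out
}

#' Tabulate read categories
#'
#' @param classified `GRanges` from [classify_reads()].
#' @return Named integer vector of counts over the four categories.
#' @export
category_counts <- function(classified) {
  table(factor(classified$category, levels = READ_CATEGORIES))
}
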