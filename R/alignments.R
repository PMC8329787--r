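# SAM FLAG bits used downstream
FLAG_UNMAPPED      <- 0x4L
FLAG_REVERSE       <- 0x10L
FLAG_SECONDARY     <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Parse one SAM alignment record
#'
#' Decodes the fields of a single SAM line: the alignment strand comes from
#' FLAG bit 0x10, the reference span from the CIGAR string, and the unmapped
#' (0x4), secondary (0x100) and supplementary (0x800) states from their FLAG
#' bits.
#'
#' @param fields Character vector of the tab-separated SAM columns (at least
#'   the 11 mandatory ones), or a single unsplit SAM line.
#' @return A list with elements `read_id`, `chrom`, `start` (1-based),
#'   `end` (inclusive), `align_strand`, `mapq`, `is_unmapped`,
#'   `is_secondary`, `is_supplementary`. `start`/`end`/`align_strand` are
#'   `NA` for unmapped records.
#' @export
parse_alignment <- function(fields) {
  if (length(fields) == 1 && grepl("\t", fields))
    fields <- strsplit(fields, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 11) stop("SAM record has fewer than 11 fields")
  flag <- suppressWarnings(as.integer(fields[2]))
  if (is.na(flag)) stop("invalid SAM FLAG: ", fields[2])
  unmapped <- bitwAnd(flag, FLAG_UNMAPPED) != 0L || fields[3] == "*"
  if (!unmapped && fields[6] == "*")
    stop("mapped SAM record with missing CIGAR")
  ref_width <- if (unmapped) NA_integer_ else cigar_ref_width(fields[6])
  pos <- suppressWarnings(as.integer(fields[4]))
  list(
    read_id = fields[1],
    chrom = if (unmapped) NA_character_ else fields[3],
    start = if (unmapped) NA_integer_ else pos,
    end = if (unmapped) NA_integer_ else pos + ref_width - 1L,
    align_strand = if (unmapped) NA_character_ else
      if (bitwAnd(flag, FLAG_REVERSE) != 0L) "-" else "+",
    mapq = suppressWarnings(as.integer(fields[5])),
    is_unmapped = unmapped,
    is_secondary = bitwAnd(flag, FLAG_SECONDARY) != 0L,
    is_supplementary = bitwAnd(flag, FLAG_SUPPLEMENTARY) != 0L
  )
}

#' Reference-space width of a CIGAR string
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of widths along the reference.
#' @export
cigar_ref_width <- function(cigar) {
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
  if (any(is.na(w))) stop("unparsable CIGAR: ",
                          paste(cigar[is.na(w)], collapse = ", "))
  w
}

#' Read aligned reads from a SAM file
#'
#' Parses a (headered) SAM text file and returns the mapped, primary
#' alignments passing the MAPQ floor as a `GRanges` whose strand is the
#' alignment strand (FLAG bit 0x10). Secondary, supplementary and unmapped
#' records are dropped, as are records below `mapq_min`. Records on
#' chromosomes absent from `keep_chroms` (when given) are skipped with a
#' single warning.
#'
#' @param path Path to a SAM file.
#' @param mapq_min MAPQ floor (default 10); alignments below it are dropped.
#' @param keep_chroms Optional character vector of admissible chromosomes.
#' @return A `GRanges` with metadata columns `read_id` and `mapq`, plus an
#'   attribute-free count of filtered records in `metadata(x)$n_filtered`
#'   (accessible via `S4Vectors::metadata`).
#' @export
read_alignments <- function(path, mapq_min = 10, keep_chroms = NULL) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$read_id <- character(0)
    S4Vectors::mcols(gr)$mapq <- integer(0)
    S4Vectors::metadata(gr) <- list(n_records = 0L, n_filtered = 0L)
    return(gr)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop("malformed SAM record at line ", which(nf < 11)[1],
         " (fewer than 11 fields)")
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6, byrow = TRUE)
  flag <- as.integer(m[, 2])
  mapq <- as.integer(m[, 5])
  unmapped <- bitwAnd(flag, FLAG_UNMAPPED) != 0L | m[, 3] == "*"
  keep <- !unmapped &
    bitwAnd(flag, FLAG_SECONDARY) == 0L &
    bitwAnd(flag, FLAG_SUPPLEMENTARY) == 0L &
    mapq >= mapq_min
  if (!is.null(keep_chroms)) {
    unknown <- keep & !(m[, 3] %in% keep_chroms)
    if (any(unknown)) {
      warning(sum(unknown), " alignment(s) on unknown chromosome(s) skipped: ",
              paste(unique(m[unknown, 3]), collapse = ", "))
      keep <- keep & !unknown
    }
  }
  n_records <- length(flag)
  m <- m[keep, , drop = FALSE]
  flag <- flag[keep]
  pos <- as.integer(m[, 4])
  w <- cigar_ref_width(m[, 6])
  gr <- GenomicRanges::GRanges(
    m[, 3],
    IRanges::IRanges(pos, width = w),
    strand = ifelse(bitwAnd(flag, FLAG_REVERSE) != 0L, "-", "+"))
  S4Vectors::mcols(gr)$read_id <- m[, 1]
  S4Vectors::mcols(gr)$mapq <- as.integer(m[, 5])
  S4Vectors::metadata(gr) <- list(n_records = n_records,
                                  n_filtered = n_records - length(gr))
  gr
}
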