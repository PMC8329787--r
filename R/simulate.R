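#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout: a compact
#' multi-chromosome yeast-like genome of 60 stranded genes, dUTP-protocol
#' 75-bp single-end reads, 3 wild-type vs 3 mutant replicates with
#' negative-binomial noise (dispersion 0.1), and 10 percent of genes
#' carrying a 4-fold antisense spike in the mutant over a wild-type
#' baseline.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param n_genes Total genes, distributed across chromosomes.
#' @param gene_length Length range (bp) for genes.
#' @param intergenic_gap Gap range (bp) between neighbouring genes.
#' @param n_replicates Replicates per condition.
#' @param read_length Read length (bp), single-end.
#' @param sense_depth Mean sense reads per gene per replicate.
#' @param antisense_fraction Fraction of genes spiked with mutant antisense.
#' @param antisense_fold Antisense fold change in the mutant for spiked genes.
#' @param antisense_baseline Mean wild-type antisense reads per gene.
#' @param dispersion Negative-binomial dispersion (phi) of all counts.
#' @param protocol Library protocol (see [LIBRARY_PROTOCOLS]).
#' @param seed Integer seed; every random choice derives from it.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_chroms = 3, chrom_length = 40000,
                              n_genes = 60, gene_length = c(500, 1500),
                              intergenic_gap = c(200, 600),
                              n_replicates = 3, read_length = 75,
                              sense_depth = 200, antisense_fraction = 0.1,
                              antisense_fold = 4, antisense_baseline = 20,
                              dispersion = 0.1,
                              protocol = "stranded_reverse", seed = 1) {
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, gene_length = gene_length,
              intergenic_gap = intergenic_gap, n_replicates = n_replicates,
              read_length = read_length, sense_depth = sense_depth,
              antisense_fraction = antisense_fraction,
              antisense_fold = antisense_fold,
              antisense_baseline = antisense_baseline,
              dispersion = dispersion, protocol = protocol,
              seed = as.integer(seed))
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_genes >= 0,
            all(cfg$gene_length > 0), diff(cfg$gene_length) >= 0,
            all(cfg$intergenic_gap >= 0), cfg$n_replicates >= 1,
            cfg$read_length > 0, cfg$sense_depth >= 0,
            cfg$antisense_fraction >= 0, cfg$antisense_fraction <= 1,
            cfg$antisense_fold >= 1, cfg$antisense_baseline >= 0,
              cfg$dispersion >= 0,
            cfg$protocol %in% LIBRARY_PROTOCOLS)
  class(cfg) <- "sim_config"
  cfg
}

#' Chromosome sizes of a simulated genome
#' @param config A `sim_config`.
#' @return Named integer vector.
#' @export
sim_chrom_sizes <- function(config) {
  stats::setNames(rep(config$chrom_length, config$n_chroms),
                  sprintf("chrS%02d", seq_len(config$n_chroms)))
}

#' Simulate a toy stranded genome annotation
#'
#' Places non-overlapping genes with random strands and random intergenic
#' gaps along each chromosome, round-robin across chromosomes. Deterministic
#' under `config$seed`. Errors when the genes cannot fit.
#'
#' @param config A `sim_config`.
#' @return A gene `GRanges` (see [load_annotation()]) with `seqlengths` set.
#' @export
simulate_genome <- function(config) {
  sizes <- sim_chrom_sizes(config)
  if (config$n_genes == 0) {
    gr <- GenomicRanges::GRanges(seqlengths = sizes)
    S4Vectors::mcols(gr)$gene_id <- character(0)
    S4Vectors::mcols(gr)$biotype <- character(0)
    return(gr)
  }
  set.seed(config$seed)
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  chrom <- character(0); start <- integer(0); end <- integer(0)
  g <- 0
  for (ci in seq_len(config$n_chroms)) {
    pos <- 1 + sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1)
    for (k in seq_len(per_chrom)) {
      if (g >= config$n_genes) break
      len <- sample(config$gene_length[1]:config$gene_length[2], 1)
      if (pos + len - 1 > sizes[ci])
        stop("genes do not fit on chromosome ", names(sizes)[ci],
             "; increase chrom_length or reduce n_genes/gene_length")
      g <- g + 1
      chrom <- c(chrom, names(sizes)[ci])
      start <- c(start, pos)
      end <- c(end, pos + len - 1L)
      pos <- pos + len +
        sample(config$intergenic_gap[1]:config$intergenic_gap[2], 1)
    }
  }
  strand <- sample(c("+", "-"), length(start), replace = TRUE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = sprintf("gene%03d", seq_along(gr)),
    biotype = rep("gene", length(gr)))
  GenomeInfoDb::seqlevels(gr) <- names(sizes)
  GenomeInfoDb::seqlengths(gr) <- sizes
  validate_annotation(gr)
}

#' Simulation truth table
#'
#' Assigns each gene its expected sense depth, wild-type antisense baseline,
#' spike flag and the antisense source interval (the central 80 percent of
#' the gene body, always covering at least half the gene so that assembled
#' units are associable with the gene).
#'
#' @param annotation Gene `GRanges` from [simulate_genome()].
#' @param config A `sim_config`.
#' @return A data.frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `sense_mean`, `antisense_baseline`, `spiked`, `antisense_fold`,
#'   `antisense_start`, `antisense_end`.
#' @export
simulate_truth <- function(annotation, config) {
  n <- length(annotation)
  set.seed(config$seed + 1L)
  n_spiked <- round(config$antisense_fraction * n)
  spiked <- rep(FALSE, n)
  if (n_spiked > 0) spiked[sample.int(n, n_spiked)] <- TRUE
  w <- BiocGenerics::width(annotation)
  margin <- floor(w * 0.1)
  data.frame(
    gene_id = annotation$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(annotation)),
    strand = as.character(BiocGenerics::strand(annotation)),
    sense_mean = rep(config$sense_depth, n),
    antisense_baseline = rep(config$antisense_baseline, n),
    spiked = spiked,
    antisense_fold = ifelse(spiked, config$antisense_fold, 1),
    antisense_start = BiocGenerics::start(annotation) + margin,
    antisense_end = BiocGenerics::end(annotation) - margin,
    stringsAsFactors = FALSE)
}

# Emit one sample's reads (GRanges in alignment-strand space) for the given
# condition. Counts are NB(mu, size = 1/phi); read starts are uniform in the
# source interval, clipped so the read stays inside the chromosome.
sim_sample_reads <- function(annotation, truth, config, condition, sample_name) {
  rl <- config$read_length
  sizes <- sim_chrom_sizes(config)
  draw <- function(mu, n) {
    if (config$dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$dispersion)
  }
  n <- nrow(truth)
  n_sense <- draw(truth$sense_mean, n)
  mu_anti <- truth$antisense_baseline *
    (if (condition == "mut") truth$antisense_fold else rep(1, n))
  n_anti <- draw(mu_anti, n)

  mk <- function(i, count, source_start, source_end, tx_strand, kind) {
    if (count == 0) return(NULL)
    lo <- source_start
    hi <- max(lo, min(source_end - rl + 1L, sizes[truth$chrom[i]] - rl + 1L))
    starts <- lo + sample.int(hi - lo + 1L, count, replace = TRUE) - 1L
    align_strand <- switch(config$protocol,
      stranded_reverse = ifelse(tx_strand == "+", "-", "+"),
      stranded_forward = tx_strand,
      unstranded = sample(c("+", "-"), count, replace = TRUE))
    data.frame(chrom = truth$chrom[i], start = starts,
               strand = align_strand,
               read_id = sprintf("%s:%s:%s:%d", kind, truth$gene_id[i],
                                 sample_name, seq_len(count)),
               stringsAsFactors = FALSE)
  }
  parts <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    g_start <- BiocGenerics::start(annotation)[i]
    g_end <- BiocGenerics::end(annotation)[i]
    parts[[2 * i - 1]] <- mk(i, n_sense[i], g_start, g_end,
                             truth$strand[i], "sense")
    anti_strand <- if (truth$strand[i] == "+") "-" else "+"
    parts[[2 * i]] <- mk(i, n_anti[i], truth$antisense_start[i],
                         truth$antisense_end[i], anti_strand, "antisense")
  }
  df <- do.call(rbind, parts)
  if (is.null(df)) {
    gr <- GenomicRanges::GRanges(seqlengths = sizes)
    S4Vectors::mcols(gr)$read_id <- character(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, width = rl),
                               strand = df$strand, seqlengths = sizes)
  S4Vectors::mcols(gr)$read_id <- df$read_id
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Simulate aligned stranded reads for every sample
#'
#' Per replicate and gene, draws a sense read count and an antisense read
#' count from the negative binomial (the antisense mean multiplied by the
#' spike fold in mutant samples of spiked genes), places reads uniformly in
#' their source interval, and sets the alignment strand by the library
#' protocol (dUTP: opposite to the transcript strand). Reads are emitted
#' pre-aligned (CIGAR `<read_length>M`, MAPQ 60) as coordinate-sorted SAM.
#' Fully deterministic under `config$seed`.
#'
#' @param annotation Gene `GRanges` from [simulate_genome()].
#' @param truth Truth table from [simulate_truth()].
#' @param config A `sim_config`.
#' @param out_dir Directory for the SAM files (created if needed).
#' @return A data.frame (the sample sheet): `sample`, `condition`, `path`.
#' @export
simulate_reads <- function(annotation, truth, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- expand.grid(rep = seq_len(config$n_replicates),
                       condition = c("wt", "mut"),
                       stringsAsFactors = FALSE)
  sheet$sample <- sprintf("%s_rep%d", sheet$condition, sheet$rep)
  sheet$path <- file.path(out_dir, paste0(sheet$sample, ".sam"))
  for (i in seq_len(nrow(sheet))) {
    set.seed(config$seed + 100L + i)
    gr <- sim_sample_reads(annotation, truth, config,
                           sheet$condition[i], sheet$sample[i])
    write_sam(gr, sheet$path[i], sim_chrom_sizes(config))
  }
  sheet[, c("sample", "condition", "path")]
}

#' Write aligned reads as a headered, coordinate-sorted SAM file
#'
#' @param reads `GRanges` with a `read_id` metadata column; strand is the
#'   alignment strand.
#' @param path Output path.
#' @param chrom_sizes Named vector of chromosome lengths for the `@SQ` lines.
#' @param mapq MAPQ written for every record (default 60).
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, chrom_sizes, mapq = 60) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                      as.integer(chrom_sizes)))
  reads <- GenomicRanges::sort(reads, ignore.strand = TRUE)
  w <- BiocGenerics::width(reads)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                  reads$read_id,
                  ifelse(as.character(BiocGenerics::strand(reads)) == "-",
                         16L, 0L),
                  as.character(GenomeInfoDb::seqnames(reads)),
                  BiocGenerics::start(reads), mapq, w, strrep("A", w))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Simulate a complete experiment to disk
#'
#' Writes the annotation (GFF3 and BED), per-sample SAM files and the truth
#' table, ready to feed [run_pipeline()].
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if needed).
#' @return List with `annotation` (GRanges), `truth` (data.frame), `samples`
#'   (sample sheet), and paths `annotation_gff`, `annotation_bed`,
#'   `truth_tsv`.
#' @export
simulate_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  annotation <- simulate_genome(config)
  truth <- simulate_truth(annotation, config)
  samples <- simulate_reads(annotation, truth, config,
                            file.path(out_dir, "reads"))
  gff <- file.path(out_dir, "annotation.gff3")
  bed <- file.path(out_dir, "annotation.bed")
  export_annotation_gff3(annotation, gff)
  write_bed(annotation, bed)
  truth_tsv <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(annotation = annotation, truth = truth, samples = samples,
       annotation_gff = gff, annotation_bed = bed, truth_tsv = truth_tsv)
}

# GFF3 export with gene-typed rows and ID/gene_id attributes that
# load_annotation() round-trips.
export_annotation_gff3 <- function(annotation, path) {
  out <- annotation
  out$type <- "gene"
  out$ID <- annotation$gene_id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Score antisense calls against the simulation truth
#'
#' Sensitivity is the fraction of spiked genes whose true antisense interval
#' overlaps at least one up-called model; the false-discovery proportion is
#' the fraction of up-called models overlapping no spiked interval (0, with
#' a flag, when nothing was called up).
#'
#' @param models Model `GRanges` from [assemble_transcripts()].
#' @param antisense_de DE data.frame for the models.
#' @param truth Truth table from [simulate_truth()].
#' @return List with `sensitivity`, `fdp`, `n_up_calls`, and `no_calls`
#'   (TRUE when FDP was undefined).
#' @export
evaluate_calls <- function(models, antisense_de, truth) {
  up_ids <- antisense_de$feature_id[antisense_de$status == "up"]
  up_models <- models[models$feature_id %in% up_ids]
  spiked <- truth[truth$spiked, , drop = FALSE]
  spike_gr <- GenomicRanges::GRanges(
    spiked$chrom,
    IRanges::IRanges(spiked$antisense_start, spiked$antisense_end))
  hit_spike <- GenomicRanges::countOverlaps(spike_gr, up_models,
                                            ignore.strand = TRUE) > 0
  sensitivity <- if (nrow(spiked) == 0) NA_real_ else mean(hit_spike)
  no_calls <- length(up_models) == 0
  fdp <- if (no_calls) 0 else
    mean(GenomicRanges::countOverlaps(up_models, spike_gr,
                                      ignore.strand = TRUE) == 0)
  list(sensitivity = sensitivity, fdp = fdp,
       n_up_calls = length(up_models), no_calls = no_calls)
}
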