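#' Run the full antisense-identification pipeline
#'
#' Orchestrates every stage on aligned stranded reads: read and filter the
#' alignments, classify them against the annotation, assemble antisense and
#' intergenic reads of the test condition into transcription units, count
#' units and sense genes per sample, test differential expression with the
#' negative-binomial exact test at the twofold / P < 0.05 screen, associate
#' units with opposite-strand genes, cross-tabulate sense vs antisense
#' regulation, build comparison gene sets, and (when a term map is given)
#' run hypergeometric over-representation at adjusted P < `enrichment_q`.
#' Outputs are written with fixed filenames and are identical for identical
#' inputs and parameters. Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param annotation Path to a GFF3/GTF/BED annotation, or a gene `GRanges`.
#' @param samples Sample sheet data.frame with columns `sample`, `condition`,
#'   `path` (SAM files).
#' @param out_dir Output directory (created; existing files overwritten).
#' @param condition_a,condition_b Reference and test condition labels
#'   (defaults `"wt"`, `"mut"`).
#' @param protocol Library protocol (default dUTP, `"stranded_reverse"`).
#' @param mapq_min MAPQ floor for alignments (default 10).
#' @param min_overlap_frac Read/feature overlap fraction (default 0.5).
#' @param max_gap,min_reads,min_length Assembly parameters
#'   (see [assemble_transcripts()]).
#' @param fc_threshold,p_threshold DE screen (defaults 2 and 0.05).
#' @param enrichment_q Adjusted-p cut-off for enrichment (default 0.05).
#' @param pseudocount Fold-change pseudocount (default 0.5).
#' @param dispersion Dispersion for the exact test: `"moderated"` (default,
#'   per-feature estimates shrunk towards the common value), `"common"`, a
#'   number, or a per-feature vector.
#' @param term_map Optional term->gene mapping (list, data.frame, or path to
#'   a 2-column TSV) for enrichment of the antisense-up gene projection.
#' @param term_universe Universe for enrichment; defaults to all annotated
#'   genes.
#' @return Invisibly, a list bundle: `annotation`, `classified`, `models`,
#'   `counts_antisense`, `counts_sense`, `de_antisense`, `de_sense`,
#'   `pairs`, `crosstab`, `sets`, `overlap_report`, `enrichment`,
#'   `lib_sizes`, `summary`.
#' @export
run_pipeline <- function(annotation, samples, out_dir,
                         condition_a = "wt", condition_b = "mut",
                         protocol = "stranded_reverse", mapq_min = 10,
                         min_overlap_frac = 0.5, max_gap = 50,
                         min_reads = 3, min_length = 100,
                         fc_threshold = 2, p_threshold = 0.05,
                         enrichment_q = 0.05, pseudocount = 0.5,
                         dispersion = "moderated", term_map = NULL,
                         term_universe = NULL) {
  stopifnot(all(c("sample", "condition", "path") %in% names(samples)))
  if (!all(c(condition_a, condition_b) %in% samples$condition))
    stop("both conditions need at least one sample")
  missing_files <- samples$path[!file.exists(samples$path)]
  if (length(missing_files) > 0)
    stop("sample file(s) not found: ", paste(missing_files, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ann <- stage("load_annotation", {
    if (is.character(annotation)) load_annotation(annotation)
    else validate_annotation(annotation)
  })

  classified <- stage("classify", {
    out <- lapply(seq_len(nrow(samples)), function(i) {
      reads <- read_alignments(samples$path[i], mapq_min = mapq_min)
      classify_reads(reads, ann, protocol = protocol,
                     min_overlap_frac = min_overlap_frac)
    })
    names(out) <- samples$sample
    out
  })
  libs <- lib_sizes(classified)

  summary_df <- stage("summarize", {
    data.frame(
      sample = samples$sample,
      condition = samples$condition,
      n_records = vapply(classified, function(x)
        S4Vectors::metadata(x)$n_records, numeric(1)),
      n_filtered_out = vapply(classified, function(x)
        S4Vectors::metadata(x)$n_filtered, numeric(1)),
      t(vapply(classified, function(x) as.numeric(category_counts(x)),
               numeric(4))) |>
        `colnames<-`(READ_CATEGORIES),
      lib_size = as.numeric(libs),
      stringsAsFactors = FALSE)
  })

  models <- stage("assemble", {
    mut_samples <- samples$sample[samples$condition == condition_b]
    pooled <- suppressWarnings(do.call(
      c, unname(lapply(classified[mut_samples], function(x) {
        S4Vectors::metadata(x) <- list()
        x
      }))))
    assemble_transcripts(pooled, max_gap = max_gap, min_reads = min_reads,
                         min_length = min_length)
  })

  counts_anti <- stage("count_antisense",
    count_reads(models, classified, min_overlap_frac = min_overlap_frac))
  counts_sense <- stage("count_sense",
    count_reads(ann, classified, min_overlap_frac = min_overlap_frac))

  de_anti <- stage("de_antisense",
    de_table(counts_anti, samples$condition, condition_a, condition_b,
             lib = libs, dispersion = dispersion,
             fc_threshold = fc_threshold, p_threshold = p_threshold,
             pseudocount = pseudocount))
  de_sense <- stage("de_sense",
    de_table(counts_sense, samples$condition, condition_a, condition_b,
             lib = libs, dispersion = dispersion,
             fc_threshold = fc_threshold, p_threshold = p_threshold,
             pseudocount = pseudocount))

  pairs <- stage("associate", associate_antisense_with_genes(models, ann))
  xtab <- stage("crosstab", crosstab_sense_antisense(de_sense, de_anti, pairs))
  sets <- stage("build_sets", build_sets(de_anti, de_sense, pairs))

  overlap_report <- stage("set_overlap", {
    combos <- list(
      c("antisense_up_genes", "sense_up"),
      c("antisense_up_genes", "sense_down"),
      c("antisense_up_genes", "ate_genes"),
      c("antisense_down_genes", "ate_genes"))
    do.call(rbind, lapply(combos, function(ab) {
      ov <- suppressWarnings(set_overlap(sets[[ab[1]]], sets[[ab[2]]]))
      data.frame(set_a = ab[1], set_b = ab[2],
                 n_a = length(sets[[ab[1]]]), n_b = length(sets[[ab[2]]]),
                 n_intersect = ov$n_intersect, n_a_only = ov$n_a_only,
                 n_b_only = ov$n_b_only, coverage = ov$coverage,
                 stringsAsFactors = FALSE)
    }))
  })

  enrichment <- NULL
  if (!is.null(term_map)) {
    enrichment <- stage("enrichment", {
      if (is.character(term_map) && length(term_map) == 1)
        term_map <- utils::read.table(term_map, sep = "\t", header = FALSE,
                                      col.names = c("term_id", "gene_id"),
                                      stringsAsFactors = FALSE)
      universe <- if (is.null(term_universe)) ann$gene_id else term_universe
      hypergeom_enrichment(sets$antisense_up_genes, term_map, universe,
                           q_max = enrichment_q)
    })
  }

  stage("write_outputs", {
    tsv <- function(x, name, rn = FALSE) {
      utils::write.table(x, emit(name), sep = "\t", quote = FALSE,
                         row.names = rn, col.names = TRUE)
    }
    if (length(models) > 0) write_bed(models, emit("antisense_models.bed"))
    write_models_gtf(models, emit("antisense_models.gtf"))
    tsv(summary_df, "read_classification_summary.tsv")
    tsv(counts_anti, "counts_antisense.tsv", rn = TRUE)
    tsv(counts_sense, "counts_sense.tsv", rn = TRUE)
    tsv(de_anti, "de_antisense.tsv")
    tsv(de_sense, "de_sense.tsv")
    tsv(pairs, "sense_antisense_pairs.tsv")
    tsv(as.data.frame.matrix(xtab$counts), "crosstab.tsv", rn = TRUE)
    tsv(xtab$detail, "crosstab_detail.tsv")
    dir.create(file.path(out_dir, "gene_sets"), showWarnings = FALSE)
    for (nm in names(sets))
      writeLines(sets[[nm]], emit(file.path("gene_sets", paste0(nm, ".txt"))))
    tsv(overlap_report, "set_overlap.tsv")
    if (!is.null(enrichment)) tsv(enrichment, "enrichment.tsv")
    params <- c(
      sprintf("condition_a=%s", condition_a),
      sprintf("condition_b=%s", condition_b),
      sprintf("protocol=%s", protocol),
      sprintf("mapq_min=%s", mapq_min),
      sprintf("min_overlap_frac=%s", min_overlap_frac),
      sprintf("max_gap=%s", max_gap),
      sprintf("min_reads=%s", min_reads),
      sprintf("min_length=%s", min_length),
      sprintf("fc_threshold=%s", fc_threshold),
      sprintf("p_threshold=%s", p_threshold),
      sprintf("enrichment_q=%s", enrichment_q),
      sprintf("pseudocount=%s", pseudocount),
      sprintf("dispersion_used=%s",
              paste(signif(unique(attr(de_anti, "dispersion")), 6),
                    collapse = ",")),
      sprintf("n_models=%d", length(models)),
      sprintf("reads_in=%s", paste(summary_df$n_records, collapse = ",")),
      sprintf("reads_conserved=%s",
              paste(summary_df$n_filtered_out + summary_df$sense +
                      summary_df$antisense + summary_df$intergenic +
                      summary_df$ambiguous == summary_df$n_records,
                    collapse = ",")))
    writeLines(params, emit("run_log.txt"))
  })

  invisible(list(annotation = ann, classified = classified, models = models,
                 counts_antisense = counts_anti, counts_sense = counts_sense,
                 de_antisense = de_anti, de_sense = de_sense, pairs = pairs,
                 crosstab = xtab, sets = sets,
                 overlap_report = overlap_report, enrichment = enrichment,
                 lib_sizes = libs, summary = summary_df))
}
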