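small_cfg <- function(...) {
  simulation_config(n_chroms = 2, chrom_length = 20000, n_genes = 16,
                    sense_depth = 60, antisense_baseline = 15, seed = 5, ...)
}

test_that("genome simulation is deterministic and places disjoint genes", {
  cfg <- small_cfg()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_equal(gr_to_df(g1), gr_to_df(g2))
  expect_length(g1, 16)
  hits <- GenomicRanges::findOverlaps(g1, ignore.strand = TRUE,
                                      drop.self = TRUE)
  expect_length(hits, 0)
  expect_length(simulate_genome(simulation_config(n_genes = 0)), 0)
  expect_error(simulate_genome(simulation_config(n_genes = 500,
                                                 chrom_length = 5000)),
               "do not fit")
})

test_that("read simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_reads(ann, truth, cfg, d1)
  s2 <- simulate_reads(ann, truth, cfg, d2)
  for (i in seq_len(nrow(s1)))
    expect_identical(readLines(s1$path[i]), readLines(s2$path[i]))
  expect_equal(nrow(s1), 6) # 3 WT + 3 mutant
})

test_that("spiked antisense intervals sit inside their gene on the opposite strand", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  expect_equal(sum(truth$spiked), round(0.1 * 16))
  expect_true(all(truth$antisense_start >= start(ann)))
  expect_true(all(truth$antisense_end <= end(ann)))
  # covering at least half the gene so pairs are associable
  expect_true(all((truth$antisense_end - truth$antisense_start + 1) >=
                    0.5 * width(ann)))
})

test_that("the dUTP strand law holds for every simulated read", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  d <- withr::local_tempdir()
  sheet <- simulate_reads(ann, truth, cfg, d)
  gene_strand <- setNames(truth$strand, truth$gene_id)
  for (p in sheet$path) {
    reads <- read_alignments(p)
    info <- strsplit(reads$read_id, ":", fixed = TRUE)
    kind <- vapply(info, `[`, "", 1)
    gene <- vapply(info, `[`, "", 2)
    tx_strand <- ifelse(kind == "sense", gene_strand[gene],
                        ifelse(gene_strand[gene] == "+", "-", "+"))
    # sequenced strand is opposite to the transcript strand, always
    expect_true(all(as.character(strand(reads)) !=
                      unname(tx_strand)))
  }
  # under the forward protocol the alignment strand equals it, always
  cfg_f <- small_cfg(protocol = "stranded_forward")
  sheet_f <- simulate_reads(ann, truth, cfg_f, withr::local_tempdir())
  reads_f <- read_alignments(sheet_f$path[1])
  info <- strsplit(reads_f$read_id, ":", fixed = TRUE)
  kind <- vapply(info, `[`, "", 1)
  gene <- vapply(info, `[`, "", 2)
  tx_strand <- ifelse(kind == "sense", gene_strand[gene],
                      ifelse(gene_strand[gene] == "+", "-", "+"))
  expect_true(all(as.character(strand(reads_f)) == unname(tx_strand)))
})

test_that("classification recovers the generating category of simulated reads", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  d <- withr::local_tempdir()
  sheet <- simulate_reads(ann, truth, cfg, d)
  reads <- read_alignments(sheet$path[sheet$sample == "mut_rep1"])
  cl <- classify_reads(reads, ann)
  kind <- vapply(strsplit(cl$read_id, ":", fixed = TRUE), `[`, "", 1)
  unamb <- cl$category != "ambiguous"
  concord <- mean(as.character(cl$category[unamb]) == kind[unamb])
  expect_gte(concord, 0.99)
})

test_that("empirical per-gene counts are calibrated to the configured mean", {
  cfg <- simulation_config(n_chroms = 1, chrom_length = 20000, n_genes = 5,
                           sense_depth = 100, antisense_baseline = 0,
                           seed = 9)
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  set.seed(99)
  n_draws <- 200
  totals <- matrix(0, nrow = n_draws, ncol = 5)
  for (i in seq_len(n_draws)) {
    gr <- antisenseq:::sim_sample_reads(ann, truth, cfg, "wt", "s")
    gene <- vapply(strsplit(gr$read_id, ":", fixed = TRUE), `[`, "", 2)
    totals[i, ] <- as.numeric(table(factor(gene, levels = ann$gene_id)))
  }
  expect_true(all(abs(colMeans(totals) - 100) / 100 < 0.05))
})

test_that("evaluate_calls scores perfect and empty call sets correctly", {
  cfg <- small_cfg()
  ann <- simulate_genome(cfg)
  truth <- simulate_truth(ann, cfg)
  sp <- truth[truth$spiked, ]
  models <- GRanges(sp$chrom, IRanges(sp$antisense_start, sp$antisense_end),
                    strand = ifelse(sp$strand == "+", "-", "+"))
  mcols(models)$feature_id <- make_feature_id(sp$chrom, sp$antisense_start,
                                              sp$antisense_end)
  de_up <- data.frame(feature_id = models$feature_id,
                      status = rep("up", length(models)))
  perfect <- evaluate_calls(models, de_up, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdp, 0)
  de_none <- data.frame(feature_id = models$feature_id,
                        status = rep("ns", length(models)))
  none <- evaluate_calls(models, de_none, truth)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fdp, 0)
  expect_true(none$no_calls)
})
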