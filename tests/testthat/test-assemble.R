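test_that("feature ids reproduce the published coordinate naming and invert", {
  expect_equal(make_feature_id("chrIII", 268287, 269650),
               "chrIII_268287_269650")
  expect_equal(make_feature_id("chrIV", 1362195, 1364695),
               "chrIV_1362195_1364695")
  back <- parse_feature_id(c("chrIII_268287_269650", "chr_un_7_10_99"))
  expect_equal(back$chrom, c("chrIII", "chr_un_7"))
  expect_equal(back$start, c(268287, 10))
  expect_equal(back$end, c(269650, 99))
  expect_error(parse_feature_id("nounderscores"), "malformed")
})

test_that("assembly merges gapped reads into strand-aware models", {
  one <- toy_classified("chr1", 101, 175, "-", "antisense")
  m1 <- assemble_transcripts(one, min_reads = 1, min_length = 1)
  expect_equal(gr_to_df(m1),
               data.frame(chrom = "chr1", start = 101, end = 175,
                          strand = "-"))
  expect_equal(m1$feature_id, "chr1_101_175")
  expect_equal(m1$n_support_reads, 1L)
  expect_equal(m1$origin, "antisense")

  reads <- toy_classified("chr1", c(11, 61, 301), c(85, 135, 375),
                          "+", rep("antisense", 3))
  m <- assemble_transcripts(reads, max_gap = 0, min_reads = 1, min_length = 1)
  expect_equal(start(m), c(11, 301))
  expect_equal(end(m), c(135, 375))
  expect_equal(m$n_support_reads, c(2L, 1L))
})

test_that("strands and filters separate clusters", {
  reads <- toy_classified("chr1", c(100, 120, 100, 120), c(200, 220, 200, 220),
                          c("+", "+", "-", "-"),
                          c("antisense", "antisense", "intergenic",
                            "intergenic"))
  m <- assemble_transcripts(reads, min_reads = 2, min_length = 50)
  expect_length(m, 2)
  expect_setequal(m$origin, c("antisense", "intergenic"))
  # sense and ambiguous reads never enter assembly
  sr <- toy_classified("chr1", c(100, 120), c(200, 220), "+",
                       c("sense", "ambiguous"))
  expect_length(assemble_transcripts(sr, min_reads = 1, min_length = 1), 0)
  # support and length floors
  expect_length(assemble_transcripts(
    toy_classified("chr1", 100, 140, "+", "antisense"),
    min_reads = 1, min_length = 100), 0)
  expect_length(assemble_transcripts(
    toy_classified("chr1", 100, 300, "+", "antisense"),
    min_reads = 2, min_length = 100), 0)
})

test_that("assembly equals the per-base coverage-union oracle on random reads", {
  set.seed(13)
  for (trial in 1:5) {
    n <- sample(50:500, 1)
    max_gap <- sample(c(0, 10, 50), 1)
    start <- sample.int(20000, n, replace = TRUE)
    reads <- toy_classified(
      sample(c("chrA", "chrB"), n, replace = TRUE),
      start, start + sample(30:120, n, replace = TRUE),
      sample(c("+", "-"), n, replace = TRUE),
      sample(c("antisense", "intergenic"), n, replace = TRUE))
    got <- assemble_transcripts(reads, max_gap = max_gap, min_reads = 1,
                                min_length = 1)
    exp <- bf_assemble(gr_to_df(reads), max_gap)
    got_df <- gr_to_df(got)
    got_df <- got_df[order(got_df$chrom, got_df$start, got_df$strand), ]
    rownames(got_df) <- rownames(exp) <- NULL
    expect_equal(got_df, exp)
  }
})

test_that("assembly is idempotent on its own models", {
  set.seed(23)
  start <- sample.int(5000, 120, replace = TRUE)
  reads <- toy_classified("chr1", start, start + 74,
                          sample(c("+", "-"), 120, replace = TRUE),
                          rep("antisense", 120))
  m1 <- assemble_transcripts(reads, min_reads = 1, min_length = 1)
  pseudo <- toy_classified(as.character(seqnames(m1)), start(m1), end(m1),
                           as.character(strand(m1)),
                           rep("antisense", length(m1)))
  m2 <- assemble_transcripts(pseudo, min_reads = 1, min_length = 1)
  expect_equal(gr_to_df(m2), gr_to_df(m1))
})

test_that("antisense units pair with opposite-strand genes only", {
  ann <- toy_annotation("chr1", c(1000, 3000), c(2000, 4000), c("+", "-"),
                        gene_id = c("gp", "gm"))
  models <- toy_classified("chr1", c(1200, 1600, 3100), c(1400, 1900, 3500),
                           c("-", "-", "-"), rep("antisense", 3))
  models <- assemble_transcripts(models, max_gap = 0, min_reads = 1,
                                 min_length = 1)
  pairs <- associate_antisense_with_genes(models, ann)
  # the "-" unit inside the "-" gene is same-strand: no pair
  expect_equal(pairs$gene_id, c("gp", "gp"))
  expect_equal(pairs$overlap_bp, width(models)[1:2])
  # two units sharing one gene keep both pairs (dedup happens at set level)
  expect_equal(length(unique(pairs$feature_id)), 2)
})

test_that("pair lists equal the all-vs-all overlap scan on random input", {
  set.seed(31)
  gs <- sample.int(30000, 40)
  ann <- toy_annotation("chr1", gs, gs + sample(200:900, 40, replace = TRUE),
                        sample(c("+", "-"), 40, replace = TRUE))
  ms <- sample.int(30000, 60)
  models <- GRanges("chr1", IRanges(ms, ms + sample(100:1200, 60,
                                                    replace = TRUE)),
                    strand = sample(c("+", "-"), 60, replace = TRUE))
  mcols(models)$feature_id <- make_feature_id("chr1", start(models),
                                              end(models))
  pairs <- associate_antisense_with_genes(models, ann)
  mdf <- gr_to_df(models); adf <- gr_to_df(ann)
  expected <- 0L
  for (i in seq_len(nrow(mdf))) for (j in seq_len(nrow(adf))) {
    ov <- min(mdf$end[i], adf$end[j]) - max(mdf$start[i], adf$start[j]) + 1
    if (ov >= 1 && mdf$strand[i] != adf$strand[j]) expected <- expected + 1L
  }
  expect_equal(nrow(pairs), expected)
  # spot-check overlap widths against the same arithmetic
  for (k in seq_len(min(nrow(pairs), 20))) {
    i <- match(pairs$feature_id[k], models$feature_id)
    j <- match(pairs$gene_id[k], ann$gene_id)
    expect_equal(pairs$overlap_bp[k],
                 min(mdf$end[i], adf$end[j]) - max(mdf$start[i],
                                                   adf$start[j]) + 1)
  }
})
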