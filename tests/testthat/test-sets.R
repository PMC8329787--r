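mk_de <- function(ids, lfc, p) {
  data.frame(feature_id = ids, log2fc = lfc, pvalue = p,
             qvalue = bh_adjust(p), status = classify_de(lfc, p),
             stringsAsFactors = FALSE)
}

test_that("gene sets project antisense features onto deduplicated genes", {
  anti <- mk_de(c("u1", "u2", "u3"), c(2.5, 2.1, -2.2), c(1e-5, 1e-4, 1e-6))
  sense <- mk_de(c("gA", "gB"), c(1.5, -0.2), c(0.01, 0.5))
  pairs <- data.frame(feature_id = c("u1", "u2", "u3"),
                      gene_id = c("gA", "gA", "gB"),
                      overlap_bp = c(100, 50, 80), stringsAsFactors = FALSE)
  s <- build_sets(anti, sense, pairs)
  expect_setequal(s$antisense_up, c("u1", "u2"))
  expect_equal(s$antisense_up_genes, "gA") # two units, one gene
  expect_equal(s$antisense_down_genes, "gB")
  expect_equal(s$sense_up, "gA")
  expect_setequal(s$ate_genes, c("gA", "gB"))

  none <- build_sets(anti, sense, pairs[0, ])
  expect_length(none$antisense_up_genes, 0)
  expect_length(none$ate_genes, 0)

  # projection never exceeds the number of pairs
  set.seed(8)
  for (i in 1:20) {
    n <- sample(1:30, 1)
    rp <- data.frame(feature_id = sample(anti$feature_id, n, replace = TRUE),
                     gene_id = sample(letters, n, replace = TRUE))
    sr <- build_sets(anti, sense, rp)
    expect_lte(length(sr$antisense_up_genes), nrow(rp))
    expect_setequal(sr$ate_genes, unique(rp$gene_id))
  }
})

test_that("set overlap performs exact Venn arithmetic", {
  eq <- set_overlap(c("a", "b"), c("b", "a"))
  expect_equal(eq$n_intersect, 2)
  expect_equal(eq$coverage, 1)
  r <- set_overlap(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(unlist(r), c(n_intersect = 2, n_a_only = 1, n_b_only = 1,
                            coverage = 2 / 3))
  expect_warning(e <- set_overlap(c("a"), character(0)), "empty")
  expect_true(is.na(e$coverage))
  set.seed(14)
  for (i in 1:20) {
    a <- sample(letters, sample(0:15, 1))
    b <- sample(letters, sample(1:15, 1))
    ov <- set_overlap(a, b)
    expect_equal(ov$n_intersect, sum(letters %in% a & letters %in% b))
    expect_equal(ov$n_a_only, sum(letters %in% a & !letters %in% b))
    expect_equal(ov$n_b_only, sum(!letters %in% a & letters %in% b))
  }
})

test_that("cross-tabulation counts distinct genes and conserves totals", {
  empty <- crosstab_sense_antisense(mk_de(character(0), numeric(0),
                                          numeric(0)),
                                    mk_de(character(0), numeric(0),
                                          numeric(0)),
                                    data.frame(feature_id = character(0),
                                               gene_id = character(0)))
  expect_true(all(empty$counts == 0))

  set.seed(25)
  n_units <- 40
  anti <- mk_de(paste0("u", 1:n_units), rnorm(n_units, 0, 2),
                runif(n_units)^2)
  sense <- mk_de(paste0("g", 1:30), rnorm(30, 0, 1.5), runif(30)^2)
  pairs <- data.frame(
    feature_id = sample(anti$feature_id, 60, replace = TRUE),
    gene_id = sample(sense$feature_id, 60, replace = TRUE),
    stringsAsFactors = FALSE)
  xt <- crosstab_sense_antisense(sense, anti, pairs)
  expect_equal(sum(xt$counts), length(unique(pairs$gene_id)))
  expect_equal(unname(lengths(xt$genes)), as.vector(xt$counts))
  # detail rows cover exactly the pairs whose unit is up
  up_units <- anti$feature_id[anti$status == "up"]
  expect_equal(nrow(xt$detail), sum(pairs$feature_id %in% up_units))
})

test_that("the published worked example reproduces its cross-tab cells", {
  xt <- set2_example_crosstab()
  expect_equal(unname(xt$counts["up", "up"]), 6L)
  expect_equal(unname(xt$counts["down", "up"]), 8L)
  expect_true("CLB6" %in% xt$genes$down_up)
  expect_equal(sum(xt$detail$gene_id == "CLB6"), 2)
})

test_that("hypergeometric enrichment matches tail-sum and draw enumeration", {
  universe <- paste0("g", 1:20)
  expect_equal(
    hypergeom_enrichment(paste0("g", 1:5),
                         list(all = universe), universe, q_max = 2)$pvalue,
    1)
  # closed-form tail: |U|=20, query 5, term 4, overlap 3
  res <- hypergeom_enrichment(paste0("g", 1:5),
                              list(t = c("g1", "g2", "g3", "g19")),
                              universe, q_max = 2)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$pvalue,
               (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) /
                 choose(20, 5))

  set.seed(52)
  u15 <- paste0("x", 1:15)
  for (i in 1:10) {
    term <- sample(u15, sample(2:8, 1))
    query <- sample(u15, sample(2:8, 1))
    got <- hypergeom_enrichment(query, list(t = term), u15, q_max = 2)
    expect_equal(got$pvalue,
                 bf_hyper_tail(u15, term, length(query), got$n_overlap))
  }

  expect_error(hypergeom_enrichment("a", list(t = "a"), character(0)),
               "empty")
  expect_warning(
    dropped <- hypergeom_enrichment(c("g1", "zz"), list(t = c("g1", "g2")),
                                    universe, q_max = 2),
    "outside the universe")
  expect_equal(dropped$n_query, 1L)
})
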