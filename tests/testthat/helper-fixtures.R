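# Toy objects and independent brute-force oracles used across tests.
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

# A GRanges annotation from vectors, validated and named.
toy_annotation <- function(chrom, start, end, strand, gene_id = NULL) {
  if (is.null(gene_id)) gene_id <- sprintf("g%02d", seq_along(start))
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr) <- DataFrame(gene_id = gene_id,
                         biotype = rep("gene", length(gr)))
  validate_annotation(gr)
}

# A classified-read GRanges built directly (bypassing classify_reads), for
# assembly/counting tests. strand = transcript strand.
toy_classified <- function(chrom, start, end, strand, category) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand)
  mcols(gr)$read_id <- sprintf("r%03d", seq_along(gr))
  mcols(gr)$category <- factor(category, levels = c("sense", "antisense",
                                                    "intergenic", "ambiguous"))
  mcols(gr)$gene_ids <- IRanges::CharacterList(
    replicate(length(gr), character(0), simplify = FALSE))
  gr
}

# O(n) overlap scan over a feature data.frame (1-based closed intervals).
bf_query_overlaps <- function(feat, chrom, qstart, qend) {
  hit <- feat$chrom == chrom & feat$start <= qend & feat$end >= qstart
  out <- feat[hit, , drop = FALSE]
  out[order(out$start, out$gene_id), , drop = FALSE]
}

# Per-base coverage-union assembly oracle: marks covered bases (plus a
# max_gap halo between reads), and reports maximal runs per chrom/strand.
bf_assemble <- function(df, max_gap) {
  out <- NULL
  for (key in unique(paste(df$chrom, df$strand))) {
    sub <- df[paste(df$chrom, df$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_e - 1 <= max_gap) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = sub$chrom[1], start = cur_s,
                                     end = cur_e, strand = sub$strand[1]))
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = sub$chrom[1], start = cur_s,
                                 end = cur_e, strand = sub$strand[1]))
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Exact binomial oracle for the dispersion-0 conditional test: enumerate all
# splits of the pooled total and sum the two tails around the observed one.
bf_binom_test <- function(s_a, s_b, L_a, L_b) {
  tot <- s_a + s_b
  if (tot == 0) return(1)
  p_b <- L_b / (L_a + L_b)
  pr <- dbinom(0:tot, tot, p_b)
  lower <- sum(pr[0:tot <= s_b])
  upper <- sum(pr[0:tot >= s_b])
  min(1, 2 * min(lower, upper))
}

# Hypergeometric tail by enumeration of every query-sized draw from the
# universe (|universe| small).
bf_hyper_tail <- function(universe, term, n_query, observed) {
  draws <- combn(universe, n_query)
  hits <- apply(draws, 2, function(d) length(intersect(d, term)))
  mean(hits >= observed)
}

# Two-sided Wilcoxon rank-sum by full enumeration of rank assignments.
bf_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  assigns <- combn(nx + ny, nx)
  ws <- apply(assigns, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu))
}

# All-pairs read/feature counting oracle.
bf_count <- function(reads_df, feat_df, min_overlap_frac) {
  sapply(seq_len(nrow(feat_df)), function(j) {
    sum(vapply(seq_len(nrow(reads_df)), function(i) {
      if (reads_df$category[i] == "ambiguous") return(FALSE)
      if (reads_df$chrom[i] != feat_df$chrom[j]) return(FALSE)
      if (reads_df$strand[i] != feat_df$strand[j]) return(FALSE)
      ov <- min(reads_df$end[i], feat_df$end[j]) -
        max(reads_df$start[i], feat_df$start[j]) + 1
      ov >= min_overlap_frac * (reads_df$end[i] - reads_df$start[i] + 1)
    }, logical(1)))
  })
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)),
             start = start(gr), end = end(gr),
             strand = as.character(strand(gr)),
             stringsAsFactors = FALSE)
}
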