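#' Build gene/feature sets from DE results and sense-antisense pairs
#'
#' Produces the standard comparison sets: up/down antisense feature sets,
#' their projections onto corresponding sense genes (deduplicated — two
#' antisense units over one gene project to one gene), up/down sense gene
#' sets, and the antisense-transcript-enriched (ATE) gene set (any gene
#' linked by at least one pair).
#'
#' @param antisense_de DE data.frame for antisense units ([de_table()]).
#' @param sense_de DE data.frame for sense genes.
#' @param pairs Pair data.frame from [associate_antisense_with_genes()].
#' @return Named list of character vectors: `antisense_up`,
#'   `antisense_down`, `antisense_up_genes`, `antisense_down_genes`,
#'   `sense_up`, `sense_down`, `ate_genes`.
#' @export
build_sets <- function(antisense_de, sense_de, pairs) {
  proj <- function(features) {
    sort(unique(pairs$gene_id[pairs$feature_id %in% features]))
  }
  anti_up <- antisense_de$feature_id[antisense_de$status == "up"]
  anti_down <- antisense_de$feature_id[antisense_de$status == "down"]
  list(
    antisense_up = anti_up,
    antisense_down = anti_down,
    antisense_up_genes = proj(anti_up),
    antisense_down_genes = proj(anti_down),
    sense_up = sense_de$feature_id[sense_de$status == "up"],
    sense_down = sense_de$feature_id[sense_de$status == "down"],
    ate_genes = sort(unique(pairs$gene_id)))
}

#' Venn-style overlap of two sets
#'
#' @param a,b Character vectors (set semantics; duplicates ignored).
#' @return List with `n_intersect`, `n_a_only`, `n_b_only` and `coverage`
#'   (`|a intersect b| / |b|`; `NA` with a warning when `b` is empty).
#' @export
set_overlap <- function(a, b) {
  a <- unique(a); b <- unique(b)
  n_int <- length(intersect(a, b))
  cov <- if (length(b) == 0) {
    warning("coverage undefined for empty reference set")
    NA_real_
  } else n_int / length(b)
  list(n_intersect = n_int,
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)),
       coverage = cov)
}

#' Cross-tabulate sense-gene regulation against antisense upregulation
#'
#' For every gene linked to at least one antisense unit, the gene's antisense
#' status is `up` if any paired unit is upregulated, else `ns`; its sense
#' status comes from `sense_de` (genes without a sense test count as `ns`).
#' Counts are over distinct genes, and the detail table lists, for genes with
#' upregulated antisense, one row per (gene, antisense unit) pair with both
#' fold changes and p-values — the layout of the published
#' sense-up/antisense-up and sense-down/antisense-up tables.
#'
#' @param sense_de DE data.frame for sense genes.
#' @param antisense_de DE data.frame for antisense units.
#' @param pairs Pair data.frame (`feature_id`, `gene_id`).
#' @return List of class `crosstab` with `counts` (3x2 matrix, sense status
#'   up/down/ns x antisense status up/ns), `genes` (list of character
#'   vectors per cell, named `<sense>_<antisense>`), and `detail`
#'   (data.frame: `gene_id`, `sense_log2fc`, `sense_pvalue`, `feature_id`,
#'   `antisense_log2fc`, `antisense_pvalue`, `sense_status`).
#' @export
crosstab_sense_antisense <- function(sense_de, antisense_de, pairs) {
  counts <- matrix(0L, nrow = 3, ncol = 2,
                   dimnames = list(sense = c("up", "down", "ns"),
                                   antisense = c("up", "ns")))
  genes <- stats::setNames(
    rep(list(character(0)), 6),
    as.vector(outer(c("up", "down", "ns"), c("up", "ns"), paste, sep = "_")))
  detail <- data.frame(gene_id = character(0), sense_log2fc = numeric(0),
                       sense_pvalue = numeric(0), feature_id = character(0),
                       antisense_log2fc = numeric(0),
                       antisense_pvalue = numeric(0),
                       sense_status = character(0), stringsAsFactors = FALSE)
  out <- structure(list(counts = counts, genes = genes, detail = detail),
                   class = "crosstab")
  if (nrow(pairs) == 0) return(out)

  anti_status <- stats::setNames(as.character(antisense_de$status),
                                 antisense_de$feature_id)
  sense_status <- stats::setNames(as.character(sense_de$status),
                                  sense_de$feature_id)
  gene_anti_up <- tapply(
    anti_status[pairs$feature_id] == "up", pairs$gene_id,
    function(z) any(z, na.rm = TRUE))
  for (g in names(gene_anti_up)) {
    s <- sense_status[g]
    if (is.na(s)) s <- "ns"
    a <- if (isTRUE(gene_anti_up[[g]])) "up" else "ns"
    counts[s, a] <- counts[s, a] + 1L
    key <- paste(s, a, sep = "_")
    genes[[key]] <- c(genes[[key]], g)
  }
  up_pairs <- pairs[pairs$feature_id %in%
                      names(anti_status)[anti_status == "up"], , drop = FALSE]
  if (nrow(up_pairs) > 0) {
    si <- match(up_pairs$gene_id, sense_de$feature_id)
    ai <- match(up_pairs$feature_id, antisense_de$feature_id)
    detail <- data.frame(
      gene_id = up_pairs$gene_id,
      sense_log2fc = sense_de$log2fc[si],
      sense_pvalue = sense_de$pvalue[si],
      feature_id = up_pairs$feature_id,
      antisense_log2fc = antisense_de$log2fc[ai],
      antisense_pvalue = antisense_de$pvalue[ai],
      sense_status = ifelse(is.na(si), "ns",
                            as.character(sense_de$status[si])),
      stringsAsFactors = FALSE)
    detail <- detail[order(detail$gene_id, detail$feature_id), , drop = FALSE]
    rownames(detail) <- NULL
  }
  structure(list(counts = counts, genes = genes, detail = detail),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Sense-gene status vs antisense upregulation (distinct genes):\n")
  print(x$counts)
  invisible(x)
}

#' Hypergeometric over-representation of a gene set in term mappings
#'
#' One-sided hypergeometric tail `P(X >= overlap)` per term
#' (`stats::phyper`), Benjamini-Hochberg adjusted across terms, ranked by
#' q-value then p-value, and filtered at `q_max`. Query members outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param term_map Named list of character vectors (term -> genes), or a
#'   two-column data.frame `(term_id, gene_id)`.
#' @param universe Character vector: the background gene universe.
#' @param q_max Adjusted-p cut-off for reporting (default 0.05; use 1 to
#'   keep every term).
#' @return A data.frame with columns `term_id`, `n_term`, `n_query`,
#'   `n_overlap`, `pvalue`, `qvalue`.
#' @export
hypergeom_enrichment <- function(query, term_map, universe, q_max = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("enrichment universe is empty")
  if (is.data.frame(term_map)) {
    term_map <- split(as.character(term_map[[2]]), as.character(term_map[[1]]))
  }
  term_map <- lapply(term_map, function(g) intersect(unique(g), universe))
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  n_u <- length(universe); n_q <- length(query)
  res <- data.frame(
    term_id = names(term_map),
    n_term = lengths(term_map),
    n_query = n_q,
    n_overlap = vapply(term_map, function(g) length(intersect(g, query)),
                       integer(1)),
    stringsAsFactors = FALSE)
  res$pvalue <- stats::phyper(res$n_overlap - 1, res$n_term,
                              n_u - res$n_term, n_q, lower.tail = FALSE)
  res$qvalue <- bh_adjust(res$pvalue)
  res <- res[order(res$qvalue, res$pvalue, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[res$qvalue < q_max, , drop = FALSE]
}
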