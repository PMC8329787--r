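#' Pearson correlation between samples
#'
#' Sample-by-sample Pearson correlation of a feature-expression matrix
#' (features in rows), as used for replicate-agreement heatmaps. Samples
#' with zero variance produce `NA` entries and a warning.
#'
#' @param mat Numeric matrix, features x samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_corr <- function(mat) {
  stopifnot(nrow(mat) >= 2)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance sample(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "),
            "; correlation undefined")
  r <- suppressWarnings(stats::cor(mat))
  diag(r)[sds > 0] <- 1
  r
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by enumeration when both sample sizes are at most `exact_below` and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_below Size bound for the exact test (default 10).
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_below = 10) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= exact_below && length(y) <= exact_below && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  # fully tied data has zero rank variance; no evidence against the null
  if (is.nan(p)) p <- 1
  p
}
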