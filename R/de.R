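#' Method-of-moments dispersion estimation
#'
#' Per-feature negative-binomial dispersion estimated on library-size-scaled
#' counts: within each condition with at least two replicates, counts are
#' scaled to the mean library size, and the condition's contribution is
#' `(var - mean) / mean^2`; contributions are pooled across conditions with
#' degrees-of-freedom weights and floored at zero (the Poisson limit). With a
#' single replicate everywhere the estimate is undefined and every feature
#' receives `prior`, with a warning.
#'
#' @param counts Count matrix (features x samples).
#' @param condition Character/factor vector of per-sample condition labels.
#' @param lib Per-sample library sizes; defaults to column sums.
#' @param prior Dispersion used when no condition has replication
#'   (default 0.1).
#' @return Named numeric vector of per-feature dispersions.
#' @export
estimate_dispersion <- function(counts, condition, lib = colSums(counts),
                                prior = 0.1) {
  condition <- as.character(condition)
  stopifnot(ncol(counts) == length(condition), length(lib) == ncol(counts))
  reps <- table(condition)
  if (all(reps < 2)) {
    warning("no condition has >= 2 replicates; using prior dispersion ", prior)
    return(stats::setNames(rep(prior, nrow(counts)), rownames(counts)))
  }
  scaled <- t(t(counts) / lib) * mean(lib)
  num <- rep(0, nrow(counts))
  den <- 0
  for (g in names(reps)[reps >= 2]) {
    x <- scaled[, condition == g, drop = FALSE]
    m <- rowMeans(x)
    v <- apply(x, 1, stats::var)
    phi_g <- ifelse(m > 0, (v - m) / m^2, 0)
    w <- sum(condition == g) - 1
    num <- num + w * phi_g
    den <- den + w
  }
  phi <- pmax(0, num / den)
  stats::setNames(phi, rownames(counts))
}

#' Exact negative-binomial test for a two-condition count split
#'
#' Conditions on the pooled total `t = sum(counts_a) + sum(counts_b)`. Under
#' the null of equal concentration, when `dispersion = 0` the observed sum in
#' condition b follows Binomial(t, L_b / (L_a + L_b)) with `L` the summed
#' library sizes; with overdispersion the split follows the conditional law
#' of two negative-binomial sums (sizes `n_g / dispersion`, means
#' proportional to `L_g`), evaluated by enumeration over the split. The
#' two-sided p-value doubles the smaller tail and is capped at 1. The fold
#' change is computed on pseudocounted library-size-normalised sums and does
#' not affect the p-value.
#'
#' @param counts_a,counts_b Non-negative per-replicate counts in the
#'   reference (a) and test (b) condition.
#' @param lib_a,lib_b Per-replicate library sizes.
#' @param dispersion Common NB dispersion (phi >= 0); 0 gives the exact
#'   binomial test.
#' @param pseudocount Added to each condition's count sum in the fold-change
#'   numerator and denominator (default 0.5).
#' @return List with `log2fc` (b over a) and `pvalue`.
#' @export
nb_exact_test <- function(counts_a, counts_b, lib_a, lib_b,
                          dispersion = 0, pseudocount = 0.5) {
  stopifnot(all(counts_a >= 0), all(counts_b >= 0),
            all(lib_a > 0), all(lib_b > 0), dispersion >= 0)
  s_a <- sum(counts_a); s_b <- sum(counts_b)
  L_a <- sum(lib_a); L_b <- sum(lib_b)
  tot <- s_a + s_b
  if (tot == 0) return(list(log2fc = 0, pvalue = 1))
  log2fc <- log2(((s_b + pseudocount) / L_b) / ((s_a + pseudocount) / L_a))
  p_b <- L_b / (L_a + L_b)
  if (dispersion == 0) {
    lower <- stats::pbinom(s_b, tot, p_b)
    upper <- stats::pbinom(s_b - 1, tot, p_b, lower.tail = FALSE)
  } else {
    tails <- nb_conditional_tails(s_b, tot, p_b,
                                  n_a = length(counts_a),
                                  n_b = length(counts_b),
                                  dispersion = dispersion)
    lower <- tails[1]; upper <- tails[2]
  }
  list(log2fc = log2fc, pvalue = min(1, 2 * min(lower, upper)))
}

# Tail probabilities P(K <= k) and P(K >= k) of the conditional split of a
# pooled NB total between conditions. Full enumeration of 0..t for modest
# totals; for large totals the support is restricted to a wide window around
# the conditional mean (and k), outside which the mass is negligible.
nb_conditional_tails <- function(k, tot, p_b, n_a, n_b, dispersion,
                                 full_below = 1e5) {
  mu_b <- tot * p_b
  mu_a <- tot - mu_b
  r_a <- n_a / dispersion
  r_b <- n_b / dispersion
  if (tot <= full_below) {
    ks <- 0:tot
  } else {
    sd_guess <- sqrt(tot * p_b * (1 - p_b) * (1 + dispersion * tot / (n_a + n_b)))
    lo <- max(0, floor(min(mu_b, k) - 50 * sd_guess - 50))
    hi <- min(tot, ceiling(max(mu_b, k) + 50 * sd_guess + 50))
    ks <- lo:hi
  }
  lp <- stats::dnbinom(ks, size = r_b, mu = mu_b, log = TRUE) +
    stats::dnbinom(tot - ks, size = r_a, mu = mu_a, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  c(sum(pr[ks <= k]), sum(pr[ks >= k]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (order-preserving, monotone); a thin wrapper over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify differential-expression status
#'
#' `up` requires `log2fc >= log2(fc_threshold)` and `pvalue < p_threshold`;
#' `down` is symmetric; everything else is `ns`. The defaults are the
#' twofold / P < 0.05 screen used for antisense-transcript selection.
#'
#' @param log2fc,pvalue Numeric vectors.
#' @param fc_threshold Fold-change cut-off (> 1; default 2).
#' @param p_threshold P-value cut-off (default 0.05).
#' @return Factor over `up`, `down`, `ns`.
#' @export
classify_de <- function(log2fc, pvalue, fc_threshold = 2, p_threshold = 0.05) {
  stopifnot(fc_threshold > 1, p_threshold > 0, p_threshold < 1)
  lfc <- log2(fc_threshold)
  status <- rep("ns", length(log2fc))
  status[log2fc >= lfc & pvalue < p_threshold] <- "up"
  status[log2fc <= -lfc & pvalue < p_threshold] <- "down"
  factor(status, levels = c("up", "down", "ns"))
}

#' Differential-expression table for a count matrix
#'
#' Runs [nb_exact_test()] per feature for `condition_b` over `condition_a`,
#' adjusts p-values with [bh_adjust()], and classifies with [classify_de()]
#' (on the raw p-value, with q-values reported alongside).
#'
#' @param counts Count matrix (features x samples).
#' @param condition Per-sample condition labels.
#' @param condition_a,condition_b Reference and test condition labels.
#' @param lib Per-sample library sizes; defaults to column sums.
#' @param dispersion Either a single dispersion, a per-feature vector,
#'   `"common"` (the median of the per-feature method-of-moments estimates
#'   over features with nonzero counts), or `"moderated"` (default): the
#'   per-feature estimates shrunk towards the common value with
#'   `prior_df` prior degrees of freedom, the standard empirical-Bayes
#'   compromise between a noisy per-feature estimate and a single shared
#'   one.
#' @param prior_df Prior degrees of freedom for `"moderated"` (default 10).
#' @param fc_threshold,p_threshold,pseudocount See [classify_de()] and
#'   [nb_exact_test()].
#' @return A data.frame with columns `feature_id`, `log2fc`, `pvalue`,
#'   `qvalue`, `status`, in input feature order; the dispersion used is kept
#'   in `attr(x, "dispersion")`.
#' @export
de_table <- function(counts, condition, condition_a, condition_b,
                     lib = colSums(counts), dispersion = "moderated",
                     fc_threshold = 2, p_threshold = 0.05,
                     pseudocount = 0.5, prior_df = 10) {
  condition <- as.character(condition)
  a <- condition == condition_a
  b <- condition == condition_b
  if (!any(a) || !any(b))
    stop("both conditions need at least one sample")
  if (is.character(dispersion)) {
    dispersion <- match.arg(dispersion, c("moderated", "common"))
    phi <- estimate_dispersion(counts[, a | b, drop = FALSE],
                               condition[a | b],
                               lib = lib[a | b])
    informative <- rowSums(counts[, a | b, drop = FALSE]) > 0
    common <- if (any(informative)) stats::median(phi[informative]) else 0
    if (dispersion == "common") {
      dispersion <- common
    } else {
      df_res <- sum(a) + sum(b) - 2
      dispersion <- (prior_df * common + df_res * phi) / (prior_df + df_res)
    }
  }
  phi_vec <- rep_len(dispersion, nrow(counts))
  res <- lapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, a], counts[i, b], lib[a], lib[b],
                  dispersion = phi_vec[i], pseudocount = pseudocount)
  })
  log2fc <- vapply(res, `[[`, numeric(1), "log2fc")
  pvalue <- vapply(res, `[[`, numeric(1), "pvalue")
  out <- data.frame(
    feature_id = rownames(counts),
    log2fc = log2fc,
    pvalue = pvalue,
    qvalue = bh_adjust(pvalue),
    status = classify_de(log2fc, pvalue, fc_threshold, p_threshold),
    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi_vec
  out
}
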