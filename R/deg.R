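# Differential expression: strict two-fold-change candidates intersected
# with Benjamini-Hochberg-controlled two-tailed Welch-test candidates,
# plus union across timepoints and gene-set overlap statistics.

#' Two-tailed Welch's t-test
#'
#' t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b) with unbiased (n-1)
#' sample variances and Welch-Satterthwaite degrees of freedom.
#' Degenerate convention when both variances are zero: equal means give
#' t = 0, p = 1; unequal means give p = 0 (infinite t, df NA).
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return list with elements \code{t}, \code{df}, \code{p}.
#' @export
welch_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("welch_t: each group needs >= 2 values")
  ma <- mean(group_a); mb <- mean(group_b)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) return(list(t = 0, df = na + nb - 2, p = 1))
    return(list(t = sign(ma - mb) * Inf, df = NA_real_, p = 0))
  }
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Row-wise Welch over two column-subsets of a matrix; returns a data.frame.
welch_t_rows <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- va == 0 & vb == 0
  if (any(degen)) {
    eq <- degen & (ma == mb)
    t[eq] <- 0; df[eq] <- na + nb - 2; p[eq] <- 1
    ne <- degen & (ma != mb)
    t[ne] <- sign(ma[ne] - mb[ne]) * Inf; df[ne] <- NA_real_; p[ne] <- 0
  }
  data.frame(mean_a = ma, mean_b = mb, t = t, df = df, p = p)
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Sorts the p-values ascending, finds the largest k with
#' p(k) <= k * alpha / m, and rejects hypotheses 1..k; equal p-values
#' always receive the same decision.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.05).
#' @return Logical vector of rejection flags, aligned with the input.
#' @export
bh_reject <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("bh_reject: p-values must lie in [0, 1]")
  }
  ord <- order(pvalues)
  ps <- pvalues[ord]
  below <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(below) > 0) {
    k <- max(below)
    # ties at the threshold p-value share the decision by construction:
    # every copy of p(k) sits at index <= k after sorting
    reject[ord[seq_len(k)]] <- TRUE
  }
  reject
}

#' Extract differentially expressed genes at one timepoint
#'
#' Per gene, computes arithmetic means of log2 values per group, flags
#' fold-change candidates when the absolute difference of means strictly
#' exceeds \code{fc_log2_threshold} (strictly more than two-fold at the
#' default of 1), runs two-tailed Welch tests, applies BH across all
#' genes at this week, and takes the intersection as DEGs.
#'
#' @param log2_matrix Gene x sample log2 expression matrix.
#' @param metadata Sample metadata (sample_id, group, week).
#' @param week Timepoint to compare.
#' @param alpha BH level, E(FDR) <= alpha (default 0.05).
#' @param fc_log2_threshold Strict log2 fold-change cutoff (default 1).
#' @return data.frame (one row per gene): gene, mean_log2_control,
#'   mean_log2_treated, delta (treated - control), t, df, p, bh_reject,
#'   fc_candidate, is_deg.
#' @export
extract_degs <- function(log2_matrix, metadata, week, alpha = 0.05,
                         fc_log2_threshold = 1) {
  metadata <- validate_metadata(metadata)
  sel <- function(group) {
    ids <- metadata$sample_id[metadata$group == group & metadata$week == week]
    ids <- intersect(ids, colnames(log2_matrix))
    if (length(ids) < 2) {
      stop("cell (", group, ", week ", week, ") has fewer than 2 samples")
    }
    log2_matrix[, ids, drop = FALSE]
  }
  xt <- sel("treated"); xc <- sel("control")
  w <- welch_t_rows(xt, xc)
  delta <- w$mean_a - w$mean_b
  fc_candidate <- abs(delta) > fc_log2_threshold
  bh <- bh_reject(w$p, alpha)
  data.frame(gene = rownames(log2_matrix),
             mean_log2_control = w$mean_b,
             mean_log2_treated = w$mean_a,
             delta = delta, t = w$t, df = w$df, p = w$p,
             bh_reject = bh, fc_candidate = fc_candidate,
             is_deg = bh & fc_candidate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Union of DEG sets across timepoints
#'
#' @param tables List of DEG tables from \code{\link{extract_degs}}.
#' @return Character vector: the union of genes flagged \code{is_deg}.
#' @export
union_degs <- function(tables) {
  if (length(tables) < 1) stop("union_degs: need at least one DEG table")
  unique(unlist(lapply(tables, function(tb) tb$gene[tb$is_deg])))
}

#' Gene-set overlap against the hypergeometric chance level
#'
#' Reports the expected overlap |A||B|/N under random draws from a
#' universe of N genes and the one-tailed Fisher exact p-value for
#' over-representation (hypergeometric upper tail, P[X >= observed]).
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param universe_size Number of genes N in the universe.
#' @return list: N, size_a, size_b, observed, expected, p.
#' @export
overlap_stats <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  K <- length(set_a); n <- length(set_b)
  if (K > universe_size || n > universe_size) {
    stop("overlap_stats: set larger than the universe")
  }
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, K, universe_size - K, n, lower.tail = FALSE)
  list(N = universe_size, size_a = K, size_b = n,
       observed = k, expected = K * n / universe_size, p = p)
}
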