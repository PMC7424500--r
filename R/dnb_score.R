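# DNB early-warning scores over a gene set S within one (group, week)
# cell of n samples:
#   I_s = mean over i in S of the sample SD s_i (n-1 denominator),
#   I_r = mean over unordered pairs i<j of (|r_ij| - c(n)),
# where r_ij is the Pearson correlation across the cell's samples and
# c(n) = E|r| for n independent bivariate standard-normal draws. The
# correction cancels the systematic inflation of |r| at n = 3-5, so I_r
# fluctuates around 0 for mutually independent genes.

#' Small-sample correction term c(n) = E|r| under independence
#'
#' Closed form for the expected absolute sample Pearson correlation of
#' two independent standard-normal variables observed on n paired
#' samples: \deqn{E|r| = 2 / [(n-2) B(1/2, (n-2)/2)].}
#' Evaluates to 2/pi (0.64), 1/2 (0.50) and 4/(3 pi) (0.42) for
#' n = 3, 4, 5. Strictly decreasing in n and tending to 0.
#'
#' @param n Integer sample size(s), each >= 3 (vectorized).
#' @return Numeric vector of correction terms in (0, 1).
#' @export
correction_term <- function(n) {
  if (any(n < 3) || any(n != round(n))) {
    stop("correction_term: n must be an integer >= 3")
  }
  2 / ((n - 2) * beta(0.5, (n - 2) / 2))
}

#' Monte-Carlo estimator of the correction term (cross-check oracle)
#'
#' Estimates E|r| by simulating \code{reps} independent pairs of
#' standard-normal n-vectors and averaging the absolute sample
#' correlations. Provided as an independent check on
#' \code{\link{correction_term}}.
#'
#' @param n Sample size, integer >= 3.
#' @param reps Number of Monte-Carlo replicates (default 1e6).
#' @return list: \code{estimate}, \code{se} (standard error), \code{reps}.
#' @export
correction_term_mc <- function(n, reps = 1e6) {
  if (n < 3) stop("correction_term_mc: n must be >= 3")
  x <- matrix(stats::rnorm(reps * n), reps, n)
  y <- matrix(stats::rnorm(reps * n), reps, n)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  a <- abs(r)
  list(estimate = mean(a), se = stats::sd(a) / sqrt(reps), reps = reps)
}

# Columns of log2_matrix belonging to one (group, week) cell.
cell_samples <- function(metadata, group, week, columns) {
  ids <- metadata$sample_id[metadata$group == group & metadata$week == week]
  intersect(ids, columns)
}

# Subset a matrix to the gene set, warning about absent genes.
subset_geneset <- function(log2_matrix, gene_set) {
  present <- intersect(gene_set, rownames(log2_matrix))
  absent <- setdiff(gene_set, rownames(log2_matrix))
  if (length(absent) > 0) {
    log_warn("genes_missing", length(absent),
             " gene(s) of the set absent from the matrix: ",
             paste(utils::head(absent, 5), collapse = ", "))
  }
  if (length(present) == 0) stop("no gene of the set is present in the matrix")
  log2_matrix[present, , drop = FALSE]
}

#' Average standard deviation I_s over a gene set in one cell
#'
#' @param log2_matrix Gene x sample log2 expression matrix.
#' @param gene_set Character vector of gene symbols.
#' @param group,week The (group, week) cell.
#' @param metadata Sample metadata.
#' @return list: \code{I_s} (mean per-gene SD, log2 units), \code{sds}
#'   (named per-gene SDs), \code{n} (sample count).
#' @export
average_sd <- function(log2_matrix, gene_set, group, week, metadata) {
  metadata <- validate_metadata(metadata)
  ids <- cell_samples(metadata, group, week, colnames(log2_matrix))
  if (length(ids) < 2) {
    stop("cell (", group, ", week ", week, ") has fewer than 2 samples")
  }
  x <- subset_geneset(log2_matrix, gene_set)[, ids, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  list(I_s = mean(sds), sds = sds, n = length(ids))
}

#' Average correlation strength I_r over a gene set in one cell
#'
#' Mean over unordered gene pairs of |r_ij| - c(n), with Pearson r across
#' the cell's samples. Constant genes are excluded with a warning; the
#' value may be negative (it fluctuates around 0 for independent genes).
#'
#' @inheritParams average_sd
#' @return list: \code{I_r}, \code{c} (correction term), \code{n}
#'   (sample count), \code{n_genes} (usable genes).
#' @export
average_correlation_strength <- function(log2_matrix, gene_set, group, week,
                                         metadata) {
  metadata <- validate_metadata(metadata)
  ids <- cell_samples(metadata, group, week, colnames(log2_matrix))
  if (length(ids) < 3) {
    stop("cell (", group, ", week ", week,
         ") has fewer than 3 samples; I_r undefined")
  }
  x <- subset_geneset(log2_matrix, gene_set)[, ids, drop = FALSE]
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0)) {
    log_warn("genes_constant", sum(s == 0),
             " constant gene(s) excluded from I_r: ",
             paste(utils::head(rownames(x)[s == 0], 5), collapse = ", "))
    x <- x[s > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("fewer than 2 usable (non-constant) genes for I_r")
  r <- stats::cor(t(x))
  cc <- correction_term(length(ids))
  pair_abs_r <- abs(r[upper.tri(r)])
  list(I_r = mean(pair_abs_r - cc), c = cc, n = length(ids),
       n_genes = nrow(x))
}

#' DNB score time course per (group, week) cell
#'
#' Computes I_s and I_r for every cell with sufficient samples; cells
#' failing the preconditions appear as rows with NA so nothing is
#' silently skipped.
#'
#' @param log2_matrix Gene x sample log2 expression matrix.
#' @param metadata Sample metadata.
#' @param gene_set The DNB gene set.
#' @return Object of class \code{dnb_scores}: list with \code{scores}
#'   (data.frame group, week, n_samples, n_genes, c, I_s, I_r) and
#'   \code{gene_sd} (data.frame gene, group, week, sd).
#' @export
score_timecourse <- function(log2_matrix, metadata, gene_set) {
  metadata <- validate_metadata(metadata)
  cells <- unique(metadata[, c("group", "week")])
  cells <- cells[order(match(cells$group, GROUP_LEVELS), cells$week), ]
  rows <- list(); sd_rows <- list()
  for (i in seq_len(nrow(cells))) {
    g <- cells$group[i]; w <- cells$week[i]
    n <- length(cell_samples(metadata, g, w, colnames(log2_matrix)))
    I_s <- NA_real_; I_r <- NA_real_; cc <- NA_real_; ng <- NA_integer_
    if (n >= 2) {
      a <- average_sd(log2_matrix, gene_set, g, w, metadata)
      I_s <- a$I_s
      ng <- length(a$sds)
      sd_rows[[length(sd_rows) + 1L]] <- data.frame(
        gene = names(a$sds), group = g, week = w, sd = unname(a$sds),
        stringsAsFactors = FALSE)
    }
    if (n >= 3 && !is.na(I_s)) {
      rr <- tryCatch(
        average_correlation_strength(log2_matrix, gene_set, g, w, metadata),
        error = function(e) NULL)
      if (!is.null(rr)) { I_r <- rr$I_r; cc <- rr$c }
    }
    rows[[i]] <- data.frame(group = g, week = w, n_samples = n,
                            n_genes = ng, c = cc, I_s = I_s, I_r = I_r,
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  if (all(is.na(scores$I_s))) stop("no scorable (group, week) cell")
  structure(list(scores = scores, gene_sd = do.call(rbind, sd_rows)),
            class = "dnb_scores")
}

#' Treated-vs-control suppression summary at one week
#'
#' Counts DNB genes whose SD is strictly lower in the treated group than
#' in the control group at the given week, and those reduced by strictly
#' more than 50%; reports the treated/control ratios of I_s and I_r as
#' percentages.
#'
#' @param scores A \code{dnb_scores} object covering both groups.
#' @param week Week to compare.
#' @return list: week, n_genes, n_decreased, n_halved, Is_ratio_pct,
#'   Ir_ratio_pct.
#' @export
suppression_summary <- function(scores, week) {
  stopifnot(inherits(scores, "dnb_scores"))
  gs <- scores$gene_sd
  sd_c <- gs[gs$group == "control" & gs$week == week, ]
  sd_t <- gs[gs$group == "treated" & gs$week == week, ]
  if (nrow(sd_c) == 0 || nrow(sd_t) == 0) {
    stop("week ", week, " not scored for both groups")
  }
  diff_genes <- c(setdiff(sd_c$gene, sd_t$gene), setdiff(sd_t$gene, sd_c$gene))
  if (length(diff_genes) > 0) {
    stop("gene sets differ between groups at week ", week, ": ",
         paste(utils::head(diff_genes, 10), collapse = ", "))
  }
  st <- sd_t$sd[match(sd_c$gene, sd_t$gene)]
  sc <- sd_c$sd
  tab <- scores$scores
  row_c <- tab[tab$group == "control" & tab$week == week, ]
  row_t <- tab[tab$group == "treated" & tab$week == week, ]
  list(week = week,
       n_genes = nrow(sd_c),
       n_decreased = sum(st < sc),
       n_halved = sum(st < 0.5 * sc),
       Is_ratio_pct = 100 * row_t$I_s / row_c$I_s,
       Ir_ratio_pct = 100 * row_t$I_r / row_c$I_r)
}
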