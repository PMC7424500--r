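# Time-evolution clustering of DEGs: per-gene z-score, 1 - Pearson
# dissimilarity, average-linkage (UPGMA) dendrogram, fixed-height cut at
# 0.5. The linkage is implemented here (not delegated) so that ties are
# broken reproducibly by lowest leaf index; tests cross-check it against
# stats::hclust and a brute-force oracle.

#' Z-score each row to mean 0 and sample SD 1
#'
#' @param matrix Numeric matrix; every row must be non-constant.
#' @return Matrix of the same shape with standardized rows.
#' @export
zscore_rows <- function(matrix) {
  stopifnot(is.matrix(matrix))
  m <- rowMeans(matrix)
  s <- sqrt(rowSums((matrix - m)^2) / (ncol(matrix) - 1))
  const <- which(s == 0 | !is.finite(s))
  if (length(const) > 0) {
    stop("cannot z-score constant row(s): ",
         paste(rownames(matrix)[const], collapse = ", "))
  }
  (matrix - m) / s
}

#' Correlation dissimilarity 1 - r between rows
#'
#' @param matrix Numeric matrix with >= 2 non-constant rows.
#' @return Symmetric matrix of 1 - Pearson correlation, zero diagonal,
#'   entries in [0, 2].
#' @export
correlation_dissimilarity <- function(matrix) {
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2) stop("need >= 2 genes for dissimilarities")
  s <- apply(matrix, 1L, stats::sd)
  if (any(s == 0)) {
    stop("constant row(s), correlation undefined: ",
         paste(rownames(matrix)[s == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(t(matrix))
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates items using the unweighted pair-group average: the
#' dissimilarity between two clusters is the mean of all cross-pair
#' dissimilarities. Ties at the minimum are broken by the lowest leaf
#' index contained in the candidate pair, so the merge sequence is
#' reproducible across platforms.
#'
#' @param dissimilarity Symmetric numeric matrix with zero diagonal.
#' @return Object of class \code{dnb_dendrogram}: a list with
#'   \code{merges} (data.frame child_a, child_b, height, size; negative
#'   children are leaves by index, positive children refer to earlier
#'   merge rows, as in \code{stats::hclust}) and \code{labels}.
#' @export
average_linkage <- function(dissimilarity) {
  d <- as.matrix(dissimilarity)
  n <- nrow(d)
  if (n < 2) stop("average_linkage: need at least 2 items")
  if (!isSymmetric(unname(d), tol = 1e-10)) stop("dissimilarity must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  active <- seq_len(n)          # column indices of live clusters in d
  id <- -seq_len(n)             # hclust-style node ids
  size <- rep(1L, n)
  minleaf <- seq_len(n)
  merges <- data.frame(child_a = integer(n - 1), child_b = integer(n - 1),
                       height = numeric(n - 1), size = integer(n - 1))
  diag(d) <- Inf

  for (step in seq_len(n - 1)) {
    dm <- min(d[active, active])
    # candidate pairs at the minimum; break ties by lowest leaf index,
    # then by the lowest leaf index of the partner
    idx <- which(d[active, active] <= dm + 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    ml1 <- pmin(minleaf[active[idx[, 1]]], minleaf[active[idx[, 2]]])
    ml2 <- pmax(minleaf[active[idx[, 1]]], minleaf[active[idx[, 2]]])
    pick <- order(ml1, ml2)[1L]
    i <- active[idx[pick, 1]]; j <- active[idx[pick, 2]]

    # deterministic child order: lower min-leaf first
    ci <- if (minleaf[i] <= minleaf[j]) i else j
    cj <- if (minleaf[i] <= minleaf[j]) j else i
    merges$child_a[step] <- id[ci]
    merges$child_b[step] <- id[cj]
    merges$height[step] <- d[i, j]
    merges$size[step] <- size[i] + size[j]

    # Lance-Williams update for the unweighted average
    rest <- setdiff(active, c(i, j))
    d[i, rest] <- d[rest, i] <-
      (size[i] * d[i, rest] + size[j] * d[j, rest]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merges = merges, labels = labels), class = "dnb_dendrogram")
}

#' Cut a dendrogram at a fixed height
#'
#' Merges with height less than or equal to \code{cutoff} (inclusive) are
#' kept; the connected components that remain are the clusters. Cluster
#' ids are numbered by the lowest leaf index they contain.
#'
#' @param dendrogram A \code{dnb_dendrogram} from
#'   \code{\link{average_linkage}}.
#' @param cutoff Height threshold (default 0.5).
#' @return list: \code{assignment} (integer cluster id per leaf, named by
#'   label) and \code{sizes} (cluster id -> size).
#' @export
cut_clusters <- function(dendrogram, cutoff = 0.5) {
  stopifnot(inherits(dendrogram, "dnb_dendrogram"))
  m <- dendrogram$merges
  n <- length(dendrogram$labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_rep <- integer(nrow(m))  # leaf representative of each merge node
  for (s in seq_len(nrow(m))) {
    ra <- if (m$child_a[s] < 0) -m$child_a[s] else node_rep[m$child_a[s]]
    rb <- if (m$child_b[s] < 0) -m$child_b[s] else node_rep[m$child_b[s]]
    node_rep[s] <- ra
    if (m$height[s] <= cutoff) parent[find(rb)] <- find(ra)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # number clusters by their lowest contained leaf index
  low <- tapply(seq_len(n), roots, min)
  ids <- match(roots, names(sort(low)))
  names(ids) <- dendrogram$labels
  list(assignment = ids, sizes = table(ids))
}

#' Cluster genes by the similarity of their time evolutions
#'
#' Builds one feature vector per gene — by default the per-(group, week)
#' cell means of log2 expression, control weeks ascending then treated
#' weeks ascending — z-scores it, converts to 1 - Pearson dissimilarity,
#' applies average linkage and cuts at the given height.
#'
#' @param log2_matrix Gene x sample log2 expression matrix.
#' @param metadata Sample metadata.
#' @param genes Genes to cluster (default: all rows).
#' @param cutoff Cut height (default 0.5).
#' @param use_cell_means Use per-cell means (default TRUE); FALSE uses all
#'   individual samples ordered by group then week.
#' @return list: \code{assignment}, \code{sizes}, \code{dendrogram},
#'   \code{features}.
#' @export
cluster_timecourses <- function(log2_matrix, metadata, genes = rownames(log2_matrix),
                                cutoff = 0.5, use_cell_means = TRUE) {
  metadata <- validate_metadata(metadata)
  missing <- setdiff(genes, rownames(log2_matrix))
  if (length(missing) > 0) {
    stop("genes not in matrix: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- log2_matrix[genes, , drop = FALSE]
  md <- metadata[order(match(metadata$group, GROUP_LEVELS), metadata$week), ]
  md <- md[md$sample_id %in% colnames(x), ]
  if (use_cell_means) {
    cells <- unique(md[, c("group", "week")])
    feats <- vapply(seq_len(nrow(cells)), function(i) {
      ids <- md$sample_id[md$group == cells$group[i] & md$week == cells$week[i]]
      rowMeans(x[, ids, drop = FALSE])
    }, numeric(nrow(x)))
    colnames(feats) <- sprintf("%s_w%g", cells$group, cells$week)
  } else {
    feats <- x[, md$sample_id, drop = FALSE]
  }
  z <- zscore_rows(feats)
  dend <- average_linkage(correlation_dissimilarity(z))
  cut <- cut_clusters(dend, cutoff)
  list(assignment = cut$assignment, sizes = cut$sizes,
       dendrogram = dend, features = feats)
}

#' Write a dendrogram as a merge-list text file
#'
#' One merge per line: child_a, child_b, height, size (hclust child
#' encoding), preceded by a header; leaf labels are written as comment
#' lines so the file round-trips.
#'
#' @param dendrogram A \code{dnb_dendrogram}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_dendrogram <- function(dendrogram, path) {
  stopifnot(inherits(dendrogram, "dnb_dendrogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# leaves: ", paste(dendrogram$labels, collapse = ",")), con)
  utils::write.table(dendrogram$merges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
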