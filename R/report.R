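# End-to-end report: DEG extraction at every week with both groups,
# union + clustering of the union, overlap of the DNB set with the DEG
# union, DNB score time course, and the spike-week suppression summary.

#' Run the full analysis and assemble a run report
#'
#' Expects an already log2-scale gene-level matrix (use
#' \code{\link{preprocess_expression}} first for raw probe-level data).
#' DEGs are extracted at every week where both groups have at least two
#' samples; the DEG union is clustered; the DNB gene set is scored per
#' cell and compared against the DEG union.
#'
#' @param log2_matrix Gene x sample log2 expression matrix.
#' @param metadata Sample metadata (sample_id, group, week).
#' @param dnb_genes Character vector: the DNB gene set.
#' @param alpha BH level (default 0.05).
#' @param fc_log2_threshold Strict log2 fold-change cutoff (default 1).
#' @param cluster_cutoff Dendrogram cut height (default 0.5).
#' @param universe_size Overlap universe; defaults to the number of genes
#'   in the matrix.
#' @param suppression_week Week for the treated-vs-control suppression
#'   summary; default: the control week with maximal I_r.
#' @return list of class \code{dnb_report}: deg_tables, deg_counts,
#'   deg_union, clusters, overlap, scores, suppression, parameters,
#'   version, timestamp.
#' @export
run_report <- function(log2_matrix, metadata, dnb_genes,
                       alpha = 0.05, fc_log2_threshold = 1,
                       cluster_cutoff = 0.5, universe_size = nrow(log2_matrix),
                       suppression_week = NULL) {
  metadata <- validate_metadata(metadata)
  weeks <- sort(unique(metadata$week))
  comparable <- Filter(function(w) {
    all(vapply(GROUP_LEVELS, function(g)
      sum(metadata$group == g & metadata$week == w) >= 2, logical(1)))
  }, weeks)
  if (length(comparable) == 0) stop("no week has both groups with >= 2 samples")

  deg_tables <- lapply(comparable, function(w)
    extract_degs(log2_matrix, metadata, w, alpha, fc_log2_threshold))
  names(deg_tables) <- paste0("week", comparable)
  deg_counts <- vapply(deg_tables, function(tb) sum(tb$is_deg), integer(1))
  deg_union <- union_degs(deg_tables)

  clusters <- NULL
  if (length(deg_union) >= 2) {
    clusters <- cluster_timecourses(log2_matrix, metadata, deg_union,
                                    cutoff = cluster_cutoff)
  }
  overlap <- overlap_stats(dnb_genes, deg_union, universe_size)
  scores <- score_timecourse(log2_matrix, metadata, dnb_genes)

  if (is.null(suppression_week)) {
    ctrl <- scores$scores[scores$scores$group == "control" &
                            !is.na(scores$scores$I_r), ]
    suppression_week <- ctrl$week[which.max(ctrl$I_r)]
  }
  suppression <- tryCatch(suppression_summary(scores, suppression_week),
                          error = function(e) NULL)

  structure(list(
    deg_tables = deg_tables,
    deg_counts = deg_counts,
    deg_union = deg_union,
    clusters = clusters,
    overlap = overlap,
    scores = scores,
    suppression = suppression,
    parameters = list(alpha = alpha, fc_log2_threshold = fc_log2_threshold,
                      cluster_cutoff = cluster_cutoff,
                      universe_size = universe_size,
                      suppression_week = suppression_week),
    version = as.character(utils::packageVersion("dnbscreen")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "dnb_report")
}

#' Persist a run report and its intermediate tables
#'
#' Writes per-week DEG TSVs, the DEG union gene set, a cluster TSV, the
#' dendrogram merge list, the score TSV, the per-gene SD TSV, the
#' suppression JSON and a summary \code{report.json} whose numbers are
#' all recomputable from the persisted intermediates.
#'
#' @param report A \code{dnb_report}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the path of \code{report.json}.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "dnb_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report$deg_tables)) {
    utils::write.table(report$deg_tables[[nm]],
                       file.path(outdir, paste0("deg_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_geneset(report$deg_union, file.path(outdir, "deg_union.txt"))
  if (!is.null(report$clusters)) {
    cl <- report$clusters
    utils::write.table(
      data.frame(gene = names(cl$assignment),
                 cluster_id = as.integer(cl$assignment),
                 cluster_size = as.integer(cl$sizes[as.character(cl$assignment)])),
      file.path(outdir, "clusters.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_dendrogram(cl$dendrogram, file.path(outdir, "dendrogram.txt"))
  }
  utils::write.table(report$scores$scores, file.path(outdir, "dnb_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$scores$gene_sd, file.path(outdir, "gene_sd.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$suppression)) {
    jsonlite::write_json(report$suppression,
                         file.path(outdir, "suppression.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  summary <- list(
    deg_counts = as.list(report$deg_counts),
    deg_union_count = length(report$deg_union),
    cluster_count = if (is.null(report$clusters)) 0L
                    else length(report$clusters$sizes),
    largest_cluster = if (is.null(report$clusters)) 0L
                      else max(as.integer(report$clusters$sizes)),
    overlap = report$overlap,
    suppression = report$suppression,
    parameters = report$parameters,
    version = report$version,
    timestamp = report$timestamp
  )
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.dnb_report <- function(x, ...) {
  cat("DNB screening report (dnbscreen ", x$version, ")\n", sep = "")
  cat("DEG counts per week:\n")
  print(x$deg_counts)
  cat("DEG union:", length(x$deg_union), "genes\n")
  if (!is.null(x$clusters)) {
    cat("Clusters:", length(x$clusters$sizes), "(largest ",
        max(as.integer(x$clusters$sizes)), " genes)\n")
  }
  ov <- x$overlap
  cat(sprintf("DNB/DEG overlap: %d observed vs %.1f expected (p = %.3g)\n",
              ov$observed, ov$expected, ov$p))
  cat("DNB scores:\n")
  print(x$scores$scores, digits = 3)
  if (!is.null(x$suppression)) {
    s <- x$suppression
    cat(sprintf(paste0("Suppression at week %g: %d/%d gene SDs decreased, ",
                       "%d halved; I_s ratio %.1f%%, I_r ratio %.1f%%\n"),
                s$week, s$n_decreased, s$n_genes, s$n_halved,
                s$Is_ratio_pct, s$Ir_ratio_pct))
  }
  invisible(x)
}
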