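# Shared fixture builders; everything is generated in code, no data files.

# Metadata for a balanced two-group design at the given weeks.
make_metadata <- function(weeks = 3:7, n_control = 4, n_treated = 4) {
  rows <- list()
  for (w in weeks) {
    if (n_control > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("control_w%g_r%d", w, seq_len(n_control)),
        group = "control", week = w, stringsAsFactors = FALSE)
    }
    if (n_treated > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("treated_w%g_r%d", w, seq_len(n_treated)),
        group = "treated", week = w, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Gaussian noise matrix keyed to metadata, optional per-gene baselines.
make_noise_matrix <- function(n_genes, metadata, sd = 0.5, baseline = 8,
                              seed = 1) {
  set.seed(seed)
  x <- baseline + matrix(rnorm(n_genes * nrow(metadata), sd = sd),
                         n_genes, nrow(metadata))
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)), metadata$sample_id)
  x
}

# Independent brute-force average linkage: recomputes every inter-cluster
# mean from the original dissimilarity matrix at each step (no
# Lance-Williams update), so it is a genuine oracle for average_linkage().
brute_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)  # leaf index sets
  heights <- numeric(n - 1)
  partitions <- list()
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        ml <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                max(min(clusters[[i]]), min(clusters[[j]])))
        better <- dij < best_d - 1e-12 ||
          (abs(dij - best_d) <= 1e-12 && !is.null(best) &&
             (ml[1] < best$ml[1] ||
                (ml[1] == best$ml[1] && ml[2] < best$ml[2])))
        if (better) { best <- list(i = i, j = j, ml = ml); best_d <- dij }
      }
    }
    heights[step] <- best_d
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions[[step]] <- lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition (for set comparison regardless of ids).
canon_partition <- function(groups) {
  sets <- lapply(groups, function(g) paste(sort(g), collapse = ","))
  unname(sort(unlist(sets)))
}

# Partition implied by a cluster assignment vector.
assignment_to_partition <- function(assignment) {
  canon_partition(split(seq_along(assignment), assignment))
}
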