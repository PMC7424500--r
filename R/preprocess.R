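# Probe-level intensities -> normalized, log2 gene-level expression:
# (1) collapse probes to gene symbols by the arithmetic mean of raw
# values, dropping unannotated probes; (2) divide each sample by its 2%
# trimmed mean; (3) log2. The order is fixed; see the methods vignette.

#' Collapse a probe-level matrix to gene level
#'
#' Probes without a gene symbol are removed; when several probes map to
#' one symbol, the per-sample value is the arithmetic mean of the probes'
#' raw values.
#'
#' @param matrix Probe-level numeric matrix (probes x samples, raw
#'   intensities), probe ids as rownames.
#' @param annotation data.frame with columns probe_id, gene_symbol (empty
#'   or NA symbol = unannotated).
#' @return Gene-level numeric matrix with unique gene symbols as rownames.
#' @export
collapse_probes <- function(matrix, annotation) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)))
  sym <- annotation$gene_symbol[match(rownames(matrix), annotation$probe_id)]
  keep <- !is.na(sym) & nzchar(trimws(sym))
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    log_warn("probes_dropped", n_dropped, " probe(s) without gene symbol removed")
  }
  if (!any(keep)) stop("empty result: no probe maps to any gene symbol")
  sub <- matrix[keep, , drop = FALSE]
  sym <- sym[keep]
  sums <- rowsum(sub, group = sym, reorder = TRUE)
  counts <- as.vector(table(sym)[rownames(sums)])
  sums / counts
}

#' Trimmed mean discarding equal fractions of low and high values
#'
#' Removes the k = floor(fraction * m) smallest and k largest values by
#' sorted position (tied values may be partially removed) and returns the
#' mean of the rest; fraction 0 gives the plain mean.
#'
#' @param values Non-empty numeric vector.
#' @param fraction Proportion trimmed from each tail, in [0, 0.5).
#' @return Scalar trimmed mean.
#' @export
trimmed_mean <- function(values, fraction = 0.02) {
  if (length(values) == 0) stop("trimmed_mean: empty input")
  if (fraction < 0 || fraction >= 0.5) stop("trimmed_mean: fraction must be in [0, 0.5)")
  m <- length(values)
  k <- floor(fraction * m)
  if (k == 0) return(mean(values))
  s <- sort(values)
  mean(s[(k + 1):(m - k)])
}

#' Normalize each sample by its 2% trimmed mean and log2-transform
#'
#' After normalization the trimmed mean of every sample is exactly 1, so
#' its log2 is 0; the whole chain is invariant to rescaling any single
#' sample by a positive constant.
#'
#' @param matrix Gene-level raw-intensity matrix; all values must be
#'   strictly positive.
#' @param fraction Trim fraction per tail (default 0.02).
#' @return log2-scale expression matrix of the same shape.
#' @export
normalize_and_log <- function(matrix, fraction = 0.02) {
  stopifnot(is.matrix(matrix))
  bad <- which(matrix <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("nonpositive value at gene '", rownames(matrix)[bad[1, 1]],
         "', sample '", colnames(matrix)[bad[1, 2]],
         "' (", nrow(bad), " nonpositive value(s) total)")
  }
  tm <- apply(matrix, 2L, trimmed_mean, fraction = fraction)
  log2(sweep(matrix, 2L, tm, "/"))
}

#' Full preprocessing chain: collapse, normalize, log2
#'
#' @param matrix Probe-level raw-intensity matrix.
#' @param annotation Probe annotation (see \code{\link{collapse_probes}});
#'   \code{NULL} if the matrix is already gene-level.
#' @param fraction Trim fraction per tail.
#' @return log2-scale gene-level expression matrix.
#' @export
preprocess_expression <- function(matrix, annotation = NULL, fraction = 0.02) {
  if (!is.null(annotation)) matrix <- collapse_probes(matrix, annotation)
  normalize_and_log(matrix, fraction = fraction)
}
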