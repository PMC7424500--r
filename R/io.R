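# File readers/writers for the pipeline's plain-text formats.
# Expression TSV: first column gene id, header row of sample ids.
# Metadata TSV: columns sample_id, group, week.
# Gene-set file: one symbol per line.
# Annotation TSV: columns probe_id, gene_symbol (empty symbol = unannotated).

GROUP_LEVELS <- c("control", "treated")

#' Read a gene-by-sample expression matrix from TSV
#'
#' The expected dialect has a header row of sample identifiers, a first
#' column of gene (or probe) identifiers, and tab-separated numeric values.
#'
#' @param path Path to a tab-separated expression table.
#' @return Numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression file ", path, ": needs a gene id column and at least one sample")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("expression file ", path, ": duplicated gene id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop("expression file ", path, ": non-numeric sample column(s): ",
         paste(names(df)[-1L][bad], collapse = ", "))
  }
  if (anyNA(mat)) stop("expression file ", path, ": missing values are not allowed")
  rownames(mat) <- ids
  mat
}

#' Write an expression matrix to TSV
#'
#' @param matrix Numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param path Output file path.
#' @param id_column Name for the gene-id column (default \code{"gene"}).
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(matrix, path, id_column = "gene") {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata (group and timepoint)
#'
#' @param path TSV with columns \code{sample_id}, \code{group},
#'   \code{week}. Group labels must be \code{control} or \code{treated}.
#' @return data.frame with columns sample_id (character), group (character),
#'   week (numeric).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "week")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata file ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  validate_metadata(df[required], context = path)
}

validate_metadata <- function(metadata, context = "metadata") {
  dup <- metadata$sample_id[duplicated(metadata$sample_id)]
  if (length(dup) > 0) {
    stop(context, ": duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(metadata$group), GROUP_LEVELS)
  if (length(bad) > 0) {
    stop(context, ": unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  }
  week <- suppressWarnings(as.numeric(metadata$week))
  if (anyNA(week)) stop(context, ": non-numeric week value(s)")
  metadata$week <- week
  metadata
}

#' Write sample metadata to TSV
#'
#' @param metadata data.frame with columns sample_id, group, week.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("sample_id", "group", "week")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set (one symbol per line)
#'
#' Blank lines and leading/trailing whitespace are tolerated; order is
#' preserved and duplicates are dropped (first occurrence kept).
#'
#' @param path Path to a plain-text gene list.
#' @return Character vector of gene symbols.
#' @export
read_geneset <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a gene set, one symbol per line
#'
#' @param genes Character vector of gene symbols.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_geneset <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' @param path TSV with columns \code{probe_id} and \code{gene_symbol};
#'   an empty symbol marks an unannotated probe.
#' @return data.frame with character columns probe_id and gene_symbol.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  required <- c("probe_id", "gene_symbol")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation file ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    stop("annotation file ", path, ": duplicated probe id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  df[required]
}

#' Read a GEO series-matrix text file (best-effort convenience)
#'
#' Parses the expression table between the
#' \code{!series_matrix_table_begin}/\code{!series_matrix_table_end}
#' markers and extracts sample titles/characteristics. Group and week
#' assignments are inferred from \code{!Sample_characteristics_ch1} lines
#' of the form \code{group: <label>} / \code{week: <number>} where
#' present; otherwise the metadata is returned with NA and flagged
#' incomplete so the caller can supply a manual metadata table.
#'
#' @param path Path to an uncompressed series-matrix text file.
#' @return list with elements \code{expression} (numeric matrix),
#'   \code{metadata} (data.frame sample_id/group/week, possibly with NAs)
#'   and \code{complete} (logical: TRUE when every sample has a
#'   recognized group and week).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("series-matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("file ", path, " is not a series-matrix file (missing table markers)")
  }
  tbl <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tbl)[1L] != "ID_REF") {
    stop("file ", path, ": malformed series-matrix header (expected ID_REF)")
  }
  ids <- as.character(tbl[[1L]])
  mat <- as.matrix(tbl[, -1L, drop = FALSE])
  if (!is.numeric(mat)) stop("file ", path, ": non-numeric expression values")
  rownames(mat) <- ids

  samples <- colnames(mat)
  header <- lines[seq_len(begin - 1L)]
  meta <- data.frame(sample_id = samples, group = NA_character_,
                     week = NA_real_, stringsAsFactors = FALSE)
  char_lines <- grep("^!Sample_characteristics_ch1\t", header, value = TRUE)
  for (ln in char_lines) {
    fields <- gsub("\"", "", strsplit(ln, "\t")[[1L]][-1L])
    if (length(fields) != length(samples)) next
    key <- tolower(trimws(sub(":.*$", "", fields)))
    val <- trimws(sub("^[^:]*:", "", fields))
    if (all(key == "group")) meta$group <- tolower(val)
    if (all(key == "week")) meta$week <- suppressWarnings(as.numeric(val))
  }
  complete <- !anyNA(meta$week) && all(meta$group %in% GROUP_LEVELS)
  list(expression = mat, metadata = meta, complete = complete)
}

# Machine-readable warning line on stderr (level WARN); tests assert on these.
log_warn <- function(code, ...) {
  msg <- paste0("WARN ", code, " ", paste0(..., collapse = ""))
  message(msg)
  invisible(msg)
}
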