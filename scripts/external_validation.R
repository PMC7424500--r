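#!/usr/bin/env Rscript
# Optional external validation on the real study data (NOT run by the
# test suite: it needs files the user must download manually).
#
# Inputs (all local; no network access is performed):
#   --series-matrix  uncompressed GEO series-matrix text file of the
#                    deposited expression series (GSE112653)
#   --metadata       TSV sample_id/group/week if the series-matrix
#                    characteristics are incomplete (optional)
#   --annotation     TSV probe_id/gene_symbol for probe collapse (optional;
#                    if omitted the matrix is assumed gene-level)
#   --dnb-genes      text file with the 147 DNB gene symbols, one per line
#   --outdir         output directory
#
# usage:
#   Rscript scripts/external_validation.R --series-matrix GSE112653_series_matrix.txt \
#       --dnb-genes dnb_genes.txt --outdir results/external
#
# The run report prints per-week DEG counts, the DEG union size, the
# DNB/DEG-union overlap against chance, the I_s/I_r time courses per
# group, and the week-5 suppression summary, and persists every
# intermediate table under --outdir.

suppressPackageStartupMessages(library(dnbscreen))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}

sm_path <- get_arg("--series-matrix")
dnb_path <- get_arg("--dnb-genes")
outdir <- get_arg("--outdir", "results/external")
if (is.null(sm_path) || is.null(dnb_path)) {
  stop("required: --series-matrix <file> --dnb-genes <file>")
}

geo <- read_geo_series_matrix(sm_path)
metadata <- if (!is.null(get_arg("--metadata"))) {
  read_metadata(get_arg("--metadata"))
} else if (geo$complete) {
  geo$metadata
} else {
  stop("series-matrix characteristics incomplete; supply --metadata")
}

raw <- geo$expression
annotation <- if (!is.null(get_arg("--annotation"))) {
  read_annotation(get_arg("--annotation"))
}
log2_matrix <- preprocess_expression(raw, annotation)

dnb_genes <- read_geneset(dnb_path)
report <- run_report(log2_matrix, metadata, dnb_genes, suppression_week = 5)
print(report)
write_report(report, outdir)
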