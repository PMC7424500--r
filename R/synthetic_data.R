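# Synthetic time-course generator planting the statistical structure the
# DNB scores target: at one "predisease" week the designated gene set
# shares a per-sample latent factor, which simultaneously inflates
# per-gene SDs (to sqrt(a^2 + sigma^2)) and pairwise correlations
# (to a^2/(a^2 + sigma^2)) in the control group; the loading is
# attenuated by kappa in the treated group. A second planted set of
# genes acquires a between-group mean shift from a later onset week.

#' Default per-cell sample counts
#'
#' Five control cells (weeks 3-7) and four treated cells (weeks 4-7) with
#' the small per-cell replicate counts typical of mouse time-course
#' microarray designs: control 5,5,5,4,5 and treated 3,4,4,4. These sizes
#' exercise all three small-sample correction terms c(3), c(4), c(5).
#'
#' @return data.frame with columns group, week, n.
#' @export
default_samples_per_cell <- function() {
  rbind(
    data.frame(group = "control", week = 3:7, n = c(5L, 5L, 5L, 4L, 5L),
               stringsAsFactors = FALSE),
    data.frame(group = "treated", week = 4:7, n = c(3L, 4L, 4L, 4L),
               stringsAsFactors = FALSE)
  )
}

#' Construct and validate a synthetic-dataset configuration
#'
#' @param n_genes Total number of genes.
#' @param n_dnb Size of the planted DNB gene set.
#' @param n_deg Number of planted between-group shifted genes.
#' @param weeks Ordered timepoints (weeks of age).
#' @param samples_per_cell data.frame(group, week, n) giving replicate
#'   counts per (group, week) cell; defaults to
#'   \code{\link{default_samples_per_cell}}.
#' @param baseline_mean_range Interval (log2 scale) from which per-gene
#'   baselines are drawn uniformly; the default [4, 12] mimics microarray
#'   dynamic range so the trimmed-mean normalization is exercised
#'   nontrivially.
#' @param noise_sd Residual SD sigma, log2 units.
#' @param dnb_loading Latent-factor loading a on the DNB genes at the
#'   spike week, log2 units.
#' @param spike_week Timepoint of the planted predisease state.
#' @param treated_attenuation kappa in [0,1] multiplying the loading in
#'   the treated group (0 = complete suppression).
#' @param deg_shift Between-group shift Delta, log2 units; the default
#'   1.2 clears the strict two-fold filter with noise.
#' @param deg_onset_week First week at which the shift applies.
#' @param seed Integer RNG seed.
#' @return An object of class \code{synth_config}.
#' @export
synth_config <- function(n_genes = 2000L,
                         n_dnb = 147L,
                         n_deg = 150L,
                         weeks = 3:7,
                         samples_per_cell = default_samples_per_cell(),
                         baseline_mean_range = c(4, 12),
                         noise_sd = 0.5,
                         dnb_loading = 1,
                         spike_week = 5,
                         treated_attenuation = 0,
                         deg_shift = 1.2,
                         deg_onset_week = 6,
                         seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_dnb = as.integer(n_dnb),
              n_deg = as.integer(n_deg), weeks = as.numeric(weeks),
              samples_per_cell = samples_per_cell,
              baseline_mean_range = as.numeric(baseline_mean_range),
              noise_sd = noise_sd, dnb_loading = dnb_loading,
              spike_week = spike_week,
              treated_attenuation = treated_attenuation,
              deg_shift = deg_shift, deg_onset_week = deg_onset_week,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid synth_config field '", field, "': ", why, call. = FALSE)
  }
  chk(cfg$n_genes >= 0 && cfg$n_dnb >= 0 && cfg$n_deg >= 0,
      "n_genes/n_dnb/n_deg", "counts must be >= 0")
  chk(cfg$n_dnb + cfg$n_deg <= cfg$n_genes, "n_dnb",
      "n_dnb + n_deg must not exceed n_genes")
  chk(cfg$noise_sd > 0, "noise_sd", "sigma must be > 0")
  chk(cfg$treated_attenuation >= 0 && cfg$treated_attenuation <= 1,
      "treated_attenuation", "kappa must lie in [0, 1]")
  chk(cfg$spike_week %in% cfg$weeks, "spike_week", "must be one of weeks")
  chk(cfg$deg_onset_week %in% cfg$weeks, "deg_onset_week", "must be one of weeks")
  chk(length(cfg$baseline_mean_range) == 2 &&
        diff(cfg$baseline_mean_range) >= 0,
      "baseline_mean_range", "must be an interval c(lo, hi)")
  spc <- cfg$samples_per_cell
  chk(is.data.frame(spc) && all(c("group", "week", "n") %in% names(spc)),
      "samples_per_cell", "needs columns group, week, n")
  chk(all(spc$group %in% GROUP_LEVELS), "samples_per_cell",
      "group labels must be control/treated")
  chk(all(spc$week %in% cfg$weeks), "samples_per_cell",
      "weeks must be a subset of config weeks")
  chk(all(spc$n >= 1), "samples_per_cell", "counts must be >= 1")
  cfg
}

#' Generate a labeled synthetic time-course expression dataset
#'
#' For gene g and sample s in cell (group gamma, week t), the log2 value
#' is \deqn{x = \mu_g + a \kappa(\gamma) 1[g \in DNB, t = spike] z_s
#'   + \Delta 1[g \in DEG, t \ge onset, \gamma = treated] + \epsilon,}
#' with z_s a per-sample standard-normal latent factor shared by all DNB
#' genes, kappa(control) = 1, kappa(treated) = \code{treated_attenuation},
#' and epsilon iid Gaussian with SD \code{noise_sd}. The same seed yields
#' an identical dataset.
#'
#' @param config A \code{\link{synth_config}}.
#' @return list of class \code{labeled_dataset}: \code{expression} (log2
#'   matrix), \code{metadata}, \code{dnb_genes}, \code{deg_genes},
#'   \code{config}.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  validate_synth_config(config)
  set.seed(config$seed)

  genes <- sprintf("gene%05d", seq_len(config$n_genes))
  dnb_genes <- genes[seq_len(config$n_dnb)]
  deg_genes <- genes[config$n_dnb + seq_len(config$n_deg)]

  spc <- config$samples_per_cell
  spc <- spc[order(match(spc$group, GROUP_LEVELS), spc$week), , drop = FALSE]
  metadata <- do.call(rbind, lapply(seq_len(nrow(spc)), function(i) {
    data.frame(
      sample_id = sprintf("%s_w%g_r%d", spc$group[i], spc$week[i],
                          seq_len(spc$n[i])),
      group = spc$group[i], week = spc$week[i], stringsAsFactors = FALSE)
  }))

  mu <- stats::runif(config$n_genes, config$baseline_mean_range[1],
                     config$baseline_mean_range[2])
  n_samples <- nrow(metadata)
  x <- mu + matrix(stats::rnorm(config$n_genes * n_samples,
                                sd = config$noise_sd),
                   config$n_genes, n_samples)
  dimnames(x) <- list(genes, metadata$sample_id)

  at_spike <- metadata$week == config$spike_week
  if (any(at_spike) && config$n_dnb > 0) {
    z <- stats::rnorm(sum(at_spike))
    kappa <- ifelse(metadata$group[at_spike] == "treated",
                    config$treated_attenuation, 1)
    x[dnb_genes, at_spike] <- x[dnb_genes, at_spike] +
      config$dnb_loading * rep(kappa * z, each = config$n_dnb)
  }
  shifted <- metadata$group == "treated" & metadata$week >= config$deg_onset_week
  if (any(shifted) && config$n_deg > 0) {
    x[deg_genes, shifted] <- x[deg_genes, shifted] + config$deg_shift
  }

  structure(list(expression = x, metadata = metadata,
                 dnb_genes = dnb_genes, deg_genes = deg_genes,
                 config = config),
            class = "labeled_dataset")
}

#' Write a synthetic dataset as the plain-text fixture set the CLI reads
#'
#' Writes \code{expression.tsv} (log2 values), \code{metadata.tsv},
#' \code{dnb_genes.txt} and \code{deg_genes.txt}; with \code{raw = TRUE}
#' also \code{expression_raw.tsv} holding the raw-intensity rendering
#' \code{2^x}.
#'
#' @param dataset A \code{labeled_dataset}.
#' @param directory Output directory (created if needed).
#' @param raw Also write the raw-intensity rendering.
#' @return Invisibly, a named character vector of file paths.
#' @export
write_fixture <- function(dataset, directory, raw = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(
    expression = file.path(directory, "expression.tsv"),
    metadata = file.path(directory, "metadata.tsv"),
    dnb_genes = file.path(directory, "dnb_genes.txt"),
    deg_genes = file.path(directory, "deg_genes.txt")
  )
  write_expression(dataset$expression, paths[["expression"]])
  write_metadata(dataset$metadata, paths[["metadata"]])
  write_geneset(dataset$dnb_genes, paths[["dnb_genes"]])
  write_geneset(dataset$deg_genes, paths[["deg_genes"]])
  if (raw) {
    paths <- c(paths, expression_raw = file.path(directory, "expression_raw.tsv"))
    write_expression(2 ^ dataset$expression, paths[["expression_raw"]])
  }
  invisible(paths)
}
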