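# Correction term, I_s, I_r, score time course, suppression summary.

test_that("correction_term matches the printed small-n values and closed forms", {
  expect_equal(round(correction_term(3), 2), 0.64)
  expect_equal(round(correction_term(4), 2), 0.50)
  expect_equal(round(correction_term(5), 2), 0.42)
  expect_equal(correction_term(3), 2 / pi, tolerance = 1e-12)
  expect_equal(correction_term(4), 0.5, tolerance = 1e-12)
  expect_equal(correction_term(5), 4 / (3 * pi), tolerance = 1e-12)
  cs <- correction_term(3:10)
  expect_true(all(diff(cs) < 0))
  expect_lt(correction_term(1000), 0.03)
  expect_error(correction_term(2), ">= 3")
})

test_that("closed form agrees with the Monte-Carlo oracle", {
  set.seed(50)
  for (n in 3:6) {
    mc <- correction_term_mc(n, reps = 2e5)
    expect_lt(abs(mc$estimate - correction_term(n)), 3 * mc$se)
  }
})

test_that("average_sd matches hand computation and scales homogeneously", {
  md <- make_metadata(weeks = 5, n_control = 2, n_treated = 0)
  x <- rbind(gA = c(0, 2), gB = c(1, 1))
  colnames(x) <- md$sample_id
  res <- average_sd(x, c("gA", "gB"), "control", 5, md)
  expect_equal(res$sds, c(gA = sqrt(2), gB = 0))
  expect_equal(res$I_s, sqrt(2) / 2)
  res3 <- average_sd(3 * x, c("gA", "gB"), "control", 5, md)
  expect_equal(res3$I_s, 3 * res$I_s)
  # constant genes -> I_s = 0
  res0 <- average_sd(x * 0 + 5, c("gA", "gB"), "control", 5, md)
  expect_equal(res0$I_s, 0)
  # missing genes excluded with a warning; none present is an error
  expect_message(resm <- average_sd(x, c("gA", "nope"), "control", 5, md),
                 "genes_missing")
  expect_equal(resm$I_s, sqrt(2))
  expect_error(suppressMessages(average_sd(x, "nope", "control", 5, md)),
               "no gene")
})

test_that("average_correlation_strength handles perfect (anti)correlation", {
  md <- make_metadata(weeks = 5, n_control = 4, n_treated = 0)
  base <- c(1, 2, 3, 5)
  x <- rbind(gA = base, gB = base, gC = 10 - base)
  colnames(x) <- md$sample_id
  # all pairwise |r| = 1 at n = 4: I_r = 1 - 0.5
  res <- average_correlation_strength(x, rownames(x), "control", 5, md)
  expect_equal(res$I_r, 0.5, tolerance = 1e-12)
  expect_equal(res$c, 0.5)
  # constant gene excluded with warning
  x2 <- rbind(x, gD = rep(2, 4))
  expect_message(
    res2 <- average_correlation_strength(x2, rownames(x2), "control", 5, md),
    "genes_constant")
  expect_equal(res2$n_genes, 3)
  # fewer than 3 samples is an error
  md2 <- make_metadata(weeks = 5, n_control = 2, n_treated = 0)
  expect_error(
    average_correlation_strength(x[, 1:2], rownames(x), "control", 5, md2),
    "fewer than 3")
})

test_that("I_r is centered at zero for independent genes", {
  # 50 independent genes, n = 5; across replicates the mean I_r should sit
  # within 3 Monte-Carlo SEs of 0 (the correction cancels E|r|)
  set.seed(51)
  md <- make_metadata(weeks = 1, n_control = 5, n_treated = 0)
  vals <- replicate(60, {
    x <- make_noise_matrix(50, md, sd = 1, seed = sample.int(1e6, 1))
    average_correlation_strength(x, rownames(x), "control", 1, md)$I_r
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("score_timecourse recovers the planted spike and suppression", {
  ds <- generate_dataset(synth_config(seed = 101))
  sc <- score_timecourse(ds$expression, ds$metadata, ds$dnb_genes)
  ctrl <- sc$scores[sc$scores$group == "control", ]
  expect_equal(ctrl$week[which.max(ctrl$I_s)], 5)
  expect_equal(ctrl$week[which.max(ctrl$I_r)], 5)
  ir_c5 <- ctrl$I_r[ctrl$week == 5]
  ir_t5 <- sc$scores$I_r[sc$scores$group == "treated" & sc$scores$week == 5]
  expect_lt(ir_t5, 0.3 * ir_c5)
  # correction terms follow the per-cell sample sizes
  expect_equal(sc$scores$c, correction_term(sc$scores$n_samples))
  # permuting sample columns leaves the scores unchanged
  perm <- sample(ncol(ds$expression))
  sc2 <- score_timecourse(ds$expression[, perm], ds$metadata, ds$dnb_genes)
  expect_equal(sc2$scores, sc$scores)
  # gene-set order invariance
  sc3 <- score_timecourse(ds$expression, ds$metadata, rev(ds$dnb_genes))
  expect_equal(sc3$scores$I_r, sc$scores$I_r)
})

test_that("cells with too few samples are reported as missing, not dropped", {
  md <- rbind(make_metadata(weeks = 5, n_control = 4, n_treated = 0),
              data.frame(sample_id = "treated_w5_r1", group = "treated",
                         week = 5, stringsAsFactors = FALSE))
  x <- make_noise_matrix(10, md, seed = 3)
  sc <- score_timecourse(x, md, rownames(x))
  trow <- sc$scores[sc$scores$group == "treated", ]
  expect_equal(nrow(trow), 1L)
  expect_true(is.na(trow$I_s) && is.na(trow$I_r))
})

test_that("suppression_summary counts reductions and ratios correctly", {
  md <- make_metadata(weeks = 5, n_control = 4, n_treated = 4)
  set.seed(52)
  ctrl <- matrix(rnorm(20 * 4, sd = 1), 20, 4)
  eps <- 1e-9
  trt <- ctrl * (0.5 - eps)  # every SD just under half of control's
  x <- cbind(ctrl, trt)
  rownames(x) <- sprintf("g%02d", 1:20)
  colnames(x) <- md$sample_id[order(md$group)]
  sc <- score_timecourse(x, md, rownames(x))
  s <- suppression_summary(sc, 5)
  expect_equal(s$n_decreased, 20)
  expect_equal(s$n_halved, 20)
  expect_lt(s$Is_ratio_pct, 50)
  # identical groups: nothing decreases, ratios are 100%
  x2 <- cbind(ctrl, ctrl)
  dimnames(x2) <- dimnames(x)
  s2 <- suppression_summary(score_timecourse(x2, md, rownames(x2)), 5)
  expect_equal(s2$n_decreased, 0)
  expect_equal(s2$n_halved, 0)
  expect_equal(s2$Is_ratio_pct, 100)
  expect_equal(s2$Ir_ratio_pct, 100)
  expect_error(suppression_summary(sc, 7), "not scored")
})

test_that("mean spike-week I_r increases with the latent loading", {
  irs <- vapply(c(0, 0.5, 1, 2), function(a) {
    vals <- vapply(1:3, function(s) {
      cfg <- synth_config(n_genes = 150, n_dnb = 60, n_deg = 0,
                          dnb_loading = a, seed = 200 + s)
      ds <- generate_dataset(cfg)
      sc <- score_timecourse(ds$expression, ds$metadata, ds$dnb_genes)
      sc$scores$I_r[sc$scores$group == "control" & sc$scores$week == 5]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(irs) > 0))
})
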