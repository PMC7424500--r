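# Welch test, BH step-up, DEG extraction, union, overlap statistics.

test_that("welch_t matches the hand-evaluated formulas and t.test", {
  res <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$t, -2 / sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(res$df, 450 / 153, tolerance = 1e-12)
  # oracle: stats::t.test on random inputs of varying size
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2))
    got <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t symmetry, antisymmetry and degenerate conventions", {
  x <- c(1.3, 2.1, 0.4, 1.8)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- rnorm(5); b <- rnorm(4)
  f <- welch_t(a, b); g <- welch_t(b, a)
  expect_equal(f$t, -g$t)
  expect_equal(f$p, g$p)
  # both variances zero
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  zed <- welch_t(c(3, 3), c(1, 1))
  expect_equal(zed$p, 0)
  expect_equal(zed$t, Inf)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("bh_reject implements the step-up rule and matches p.adjust", {
  expect_equal(bh_reject(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_reject(c(0.001, 0.2, 0.9), 0.05), c(TRUE, FALSE, FALSE))
  expect_equal(bh_reject(rep(1, 5)), rep(FALSE, 5))
  expect_identical(bh_reject(numeric(0)), logical(0))
  # oracle: rejection at level alpha <=> BH-adjusted p <= alpha
  set.seed(20)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.2)
    expect_identical(bh_reject(p, alpha),
                     p.adjust(p, method = "BH") <= alpha)
  }
  # tied p-values share one decision
  p <- c(0.04, 0.04, 0.04, 0.9)
  flags <- bh_reject(p, 0.05)
  expect_true(all(flags[1:3]) || all(!flags[1:3]))
})

test_that("extract_degs recovers a strongly planted toy exactly", {
  md <- make_metadata(weeks = 5, n_control = 5, n_treated = 5)
  set.seed(7)
  x <- make_noise_matrix(100, md, sd = 0.1, seed = 7)
  planted <- c("g001", "g050", "g100")
  x[planted, md$group == "treated"] <- x[planted, md$group == "treated"] + 3
  tb <- extract_degs(x, md, week = 5)
  expect_setequal(tb$gene[tb$is_deg], planted)
  # DEG flag is exactly the conjunction of its two candidate flags
  expect_identical(tb$is_deg, tb$bh_reject & tb$fc_candidate)
  expect_true(all(tb$p >= 0 & tb$p <= 1))
})

test_that("the fold-change filter is strict at |delta| = 1", {
  md <- make_metadata(weeks = 5, n_control = 2, n_treated = 2)
  # gene gA: delta exactly 1.0; gene gB: delta 1.2
  x <- rbind(gA = c(0.5, 1.5, 1.5, 2.5), gB = c(0.4, 1.6, 1.6, 2.8))
  colnames(x) <- md$sample_id  # control first two, treated last two
  md_ord <- md[order(md$group), ]
  tb <- extract_degs(x, md_ord, week = 5)
  expect_equal(tb$delta[tb$gene == "gA"], 1.0)
  expect_false(tb$fc_candidate[tb$gene == "gA"])
  expect_true(tb$fc_candidate[tb$gene == "gB"])
})

test_that("extract_degs is invariant to sample and gene ordering", {
  md <- make_metadata(weeks = 4, n_control = 4, n_treated = 3)
  x <- make_noise_matrix(50, md, sd = 0.5, seed = 15)
  x["g010", md$group == "treated"] <- x["g010", md$group == "treated"] + 4
  base <- extract_degs(x, md, week = 4)
  perm_s <- sample(ncol(x)); perm_g <- sample(nrow(x))
  shuffled <- extract_degs(x[perm_g, perm_s], md[sample(nrow(md)), ], week = 4)
  reord <- shuffled[match(base$gene, shuffled$gene), ]
  expect_equal(reord$p, base$p, ignore_attr = TRUE)
  expect_equal(reord$is_deg, base$is_deg, ignore_attr = TRUE)
  expect_error(extract_degs(x, md, week = 99), "week 99")
})

test_that("union_degs unions final flags across weeks", {
  mk <- function(genes, flags) data.frame(gene = genes, is_deg = flags)
  t1 <- mk(c("A", "B", "C"), c(TRUE, TRUE, FALSE))
  t2 <- mk(c("A", "B", "C"), c(FALSE, TRUE, TRUE))
  expect_setequal(union_degs(list(t1, t2)), c("A", "B", "C"))
  expect_setequal(union_degs(list(t1, t1)), c("A", "B"))
  t3 <- mk(c("D", "E", "F"), c(TRUE, TRUE, TRUE))
  expect_length(union_degs(list(t1, t3)), 5)
  expect_error(union_degs(list()), "at least one")
})

test_that("overlap_stats reproduces the worked example and edge cases", {
  A <- sprintf("a%03d", 1:147)
  B <- c(A[1:6], sprintf("b%03d", 1:690))  # |B| = 696, overlap 6
  res <- overlap_stats(A, B, 24217)
  expect_equal(round(res$expected, 1), 4.2)
  expect_equal(round(res$p, 2), 0.25)
  expect_equal(res$observed, 6)
  # A = entire universe
  U <- sprintf("u%02d", 1:20)
  res2 <- overlap_stats(U, U[1:7], 20)
  expect_equal(res2$expected, 7)
  expect_equal(res2$p, 1)
  expect_error(overlap_stats(U, U, 10), "universe")
})

test_that("overlap p agrees with a brute-force hypergeometric tail sum", {
  # independent oracle: explicit sum of choose() terms, N <= 50
  brute_tail <- function(k, K, n, N) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
  }
  set.seed(30)
  U <- sprintf("u%02d", 1:50)
  for (i in 1:25) {
    K <- sample(1:30, 1); n <- sample(1:30, 1)
    A <- sample(U, K); B <- sample(U, n)
    res <- overlap_stats(A, B, 50)
    expect_equal(res$p, brute_tail(res$observed, K, n, 50), tolerance = 1e-12)
  }
})
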