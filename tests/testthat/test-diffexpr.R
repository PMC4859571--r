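test_that("student_t matches the classical fit and honours its conventions", {
  # identical constant groups: nothing to distinguish
  st <- student_t(c(1, 1), c(1, 1))
  expect_equal(st$t, 0)
  expect_equal(st$p, 1)

  # random small vectors against stats::t.test
  set.seed(31)
  for (i in 1:200) {
    x <- rnorm(sample(2:8, 1)); y <- rnorm(sample(2:8, 1), mean = runif(1, -1, 1))
    got <- student_t(x, y)
    ora <- oracle_t(x, y)
    expect_equal(got$t, ora$t, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
  }

  expect_error(student_t(1, c(1, 2)), "at least two")
  # zero variance, unequal means: signed infinity
  st2 <- student_t(c(1, 1), c(2, 2))
  expect_true(is.infinite(st2$t) && st2$t > 0)
  expect_equal(st2$p, 0)
})

test_that("null t-test p-values are uniform", {
  set.seed(77)
  X <- matrix(rnorm(10000 * 20), nrow = 10000)
  st <- lobulescreen:::row_t_stats(X, 1:10, 11:20)
  ks <- ks.test(st$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni adjustment is the capped product and order preserving", {
  expect_equal(bonferroni(0.01, m = 10), 0.1)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50)
  adj <- bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in p
  expect_equal(adj, pmin(1, p * 50))
  # NA (untested) entries do not inflate the test count
  expect_equal(bonferroni(c(0.1, NA)), c(0.1, NA))
})

test_that("sam_d follows the relative-difference formula and the t identity", {
  expect_equal(sam_d(c(1, 2, 3), c(2, 1, 3))$d, 0)

  # hand-sized input against step-by-step arithmetic
  x <- c(0.2, 1.1, 0.7); y <- c(2.3, 1.9, 2.8)
  for (s0 in c(0, 0.1, 1)) {
    got <- sam_d(x, y, s0 = s0)
    ora <- oracle_sam_d(x, y, s0)
    expect_equal(got$d, ora$d, tolerance = 1e-12)
    expect_equal(got$s, ora$s, tolerance = 1e-12)
  }

  # s0 = 0 recovers the pooled-variance t statistic exactly
  set.seed(41)
  for (i in 1:100) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(sam_d(x, y, s0 = 0)$d, student_t(x, y)$t, tolerance = 1e-12)
  }

  # zero scatter and zero s0 with unequal means: flagged infinity
  expect_true(is.infinite(sam_d(c(1, 1), c(2, 2), s0 = 0)$d))
  expect_error(sam_d(c(1, 2), c(1, 2), s0 = -1), "s0")
})

test_that("choose_s0 equals the exhaustive grid-search oracle", {
  set.seed(13)
  n <- 300
  s <- rexp(n) + 0.05
  r <- rnorm(n, sd = s + 0.2)  # heteroscedastic so the argmin is interior-ish
  got <- choose_s0(s, r)
  ora <- oracle_choose_s0(s, r, n_windows = 30)
  expect_equal(as.numeric(got), ora, tolerance = 1e-12)
  expect_gte(as.numeric(got), 0)
  # fallback path below 10 genes
  s5 <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_message(s0small <- choose_s0(s5, rnorm(5)), "median")
  expect_equal(as.numeric(s0small), median(s5))
})

test_that("choose_s0 is stable across seeds on homoscedastic data", {
  pcts <- integer(50)
  set.seed(7)
  for (i in 1:50) {
    X <- matrix(rnorm(2000 * 24), nrow = 2000)
    st <- lobulescreen:::row_sam_stats(X, 1:12, 13:24, 0)
    pcts[i] <- attr(choose_s0(st$s, st$r), "percentile")
  }
  expect_gte(max(table(pcts)) / 50, 0.9)
})

test_that("sam_screen q-values equal exhaustive enumeration on a tiny instance", {
  set.seed(3)
  X <- matrix(rnorm(20 * 6), nrow = 20)
  X[1:2, 4:6] <- X[1:2, 4:6] + 3  # two up-regulated genes
  rownames(X) <- sprintf("g%02d", 1:20)
  g <- factor(rep(c("a", "b"), each = 3))
  t0 <- Sys.time()
  got <- sam_screen(X, group = g, s0 = 0.2, n_perm = 5)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 1)
  expect_true(attr(got, "exact"))
  expect_equal(attr(got, "n_perm_used"), choose(6, 3))  # all 20 balanced perms

  ora <- oracle_sam_full(X, idx_a = 1:3, s0 = 0.2)
  expect_equal(got$d, ora$d, tolerance = 1e-12)
  expect_equal(got$q, ora$q, tolerance = 1e-10)
  expect_equal(sort(got$d_expected), ora$d_expected_sorted, tolerance = 1e-12)
  # q behaves like an FDR and is monotone in |d| within sign
  expect_true(all(got$q >= 0 & got$q <= 1))
  up <- got[got$d > 0, ]
  expect_true(all(diff(up$q[order(up$d)]) <= 1e-12))
})

test_that("the degenerate identity permutation gives FDR capped at 1", {
  set.seed(9)
  X <- matrix(rnorm(15 * 6), nrow = 15)
  tested <- 1:15
  perms <- matrix(1:3, ncol = 1)  # only the original labelling
  ps <- lobulescreen:::perm_d_sorted(X, tested, perms, 3, 0.1)
  obs <- lobulescreen:::row_sam_stats(X, 1:3, 4:6, 0.1)
  expect_equal(ps[, 1], sort(obs$d), tolerance = 1e-12)
  # expected = observed, so at delta 0 the false count equals the call count
  dsort <- ps[, 1]
  cu <- min(dsort[dsort > 0]); cl <- max(dsort[dsort < 0])
  n_called <- sum(dsort >= cu) + sum(dsort <= cl)
  n_false <- sum(ps[, 1] >= cu) + sum(ps[, 1] <= cl)
  expect_equal(n_false, n_called)
  expect_lte(min(1, n_false / n_called), 1)
})

test_that("permutation sampling is seeded and switches to exact when feasible", {
  atl <- simulate_atlas(tiny_config(n_genes = 40, seed = 2))
  roi <- tiny_roi(atl)
  s1 <- sam_screen(roi, n_perm = 30, seed = 5, max_exact = 0)
  s2 <- sam_screen(roi, n_perm = 30, seed = 5, max_exact = 0)
  expect_identical(s1$q, s2$q)
  expect_false(attr(s1, "exact"))
  # small voxel sets are enumerated regardless of n_perm
  X <- matrix(rnorm(12 * 6), nrow = 12)
  s3 <- sam_screen(X, group = factor(rep(1:2, each = 3)), s0 = 0.1, n_perm = 3)
  expect_true(attr(s3, "exact"))
})

test_that("top-N union obeys its set algebra and ranking ties", {
  atl <- simulate_atlas(tiny_config(n_genes = 30, seed = 3))
  sc <- screen_genes(tiny_roi(atl), top_n = 5, n_perm = 20)
  expect_equal(sum(sc$in_top_t), 5)
  expect_equal(sum(sc$in_top_sam), 5)
  expect_gte(sum(sc$in_union), max(sum(sc$in_top_t), sum(sc$in_top_sam)))
  expect_lte(sum(sc$in_union), 10)
  # n >= gene count selects everything tested
  sc_all <- top_n_union(sc, n = 1000)
  expect_true(all(sc_all$in_union[sc_all$tested]))
  # ranks are a permutation of the tested genes
  expect_setequal(sc$rank_t[sc$tested], seq_len(sum(sc$tested)))
  expect_setequal(sc$rank_sam[sc$tested], seq_len(sum(sc$tested)))
})

test_that("tidiers expose the screen result as plain tables", {
  atl <- simulate_atlas(tiny_config(n_genes = 25, seed = 4))
  sc <- screen_genes(tiny_roi(atl), top_n = 5, n_perm = 20)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "screen_result"))
  gl <- glance(sc)
  expect_equal(gl$n_genes, 25)
  expect_equal(gl$n_union, sum(sc$in_union))
})
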