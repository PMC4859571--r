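make_roi <- function() {
  atl <- simulate_atlas(tiny_config(seed = 7))
  em <- build_expression_matrix(atl)
  list(atl = atl, em = em, roi = select_roi_pair(em))
}

test_that("detectability requires expression in exactly one region", {
  f <- make_roi()
  det <- detectability(f$roi)
  planted <- planted_genes(f$atl)
  # region-restricted genes pass; pan-expressed null genes fail
  expect_true(all(det$pass_detect[det$gene_id %in% planted]))
  nulls <- setdiff(det$gene_id, planted)
  expect_lt(mean(det$pass_detect[det$gene_id %in% nulls]), 0.05)
  # direction points at the expressing ROI
  post <- f$atl$truth$gene_id[f$atl$truth$direction == "posterior"]
  expect_true(all(det$direction[det$gene_id %in% post] == "posterior"))
  expect_error(detectability(f$roi, min_fraction = 0), "min_fraction")
})

test_that("detect fractions are monotone under a rising threshold", {
  f <- make_roi()
  thresholds <- seq(0, 4, by = 0.5)
  sweep <- lapply(thresholds, function(th) detectability(f$roi, threshold = th))
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(sweep[[i]]$detect_fraction_a <= sweep[[i - 1]]$detect_fraction_a))
    expect_true(all(sweep[[i]]$detect_fraction_b <= sweep[[i - 1]]$detect_fraction_b))
    # a gene undetectable in both ROIs can never become detectable
    dead <- !sweep[[i - 1]]$detectable_a & !sweep[[i - 1]]$detectable_b
    expect_false(any(sweep[[i]]$detectable_a[dead] | sweep[[i]]$detectable_b[dead]))
  }
  # brute-force recount at one threshold
  th <- 1.5
  det <- detectability(f$roi, threshold = th)
  g1 <- which(f$roi$genes == det$gene_id[5])
  a_cols <- f$roi$group == "anterior"
  expect_equal(det$detect_fraction_a[5], mean(f$roi$values[g1, a_cols] > th))
})

test_that("pattern concordance scores self, inverse and affine transforms", {
  lm <- default_lobule_map(c(20, 8, 8))
  pat <- survival_pattern(lm)
  prof_self <- tibble::tibble(gene_id = "self", label = pat$label,
                              mean_energy = pat$survival)
  prof_inv <- tibble::tibble(gene_id = "inv", label = pat$label,
                             mean_energy = 1 - pat$survival)
  prof_affine <- tibble::tibble(gene_id = "aff", label = pat$label,
                                mean_energy = 3 + 10 * pat$survival)
  prof_flat <- tibble::tibble(gene_id = "flat", label = pat$label,
                              mean_energy = 2)
  conc <- pattern_concordance(
    dplyr::bind_rows(prof_self, prof_inv, prof_affine, prof_flat), pat)
  expect_equal(conc$concordance[conc$gene_id == "self"], 1)
  expect_equal(conc$concordance[conc$gene_id == "inv"], -1)
  expect_equal(conc$concordance[conc$gene_id == "aff"], 1)
  expect_false(conc$scoreable[conc$gene_id == "flat"])
  expect_error(pattern_concordance(prof_self[1:2, ], pat), "3 lobule segments")
})

test_that("random profiles rarely reach the concordance threshold", {
  lm <- default_lobule_map(c(20, 8, 8))
  pat <- survival_pattern(lm)
  set.seed(55)
  n <- 1000
  prof <- tibble::tibble(
    gene_id = rep(sprintf("r%04d", 1:n), each = nrow(pat)),
    label = rep(pat$label, n),
    mean_energy = runif(n * nrow(pat))
  )
  conc <- pattern_concordance(prof, pat)
  # oracle: under a random profile the score follows the null distribution
  # of the Pearson correlation, t = r sqrt(k-2)/sqrt(1-r^2) ~ t(k-2), with
  # k = 7 segments. Acceptance at |r| >= 0.7 is then a ~8% event and
  # |r| < 0.5 a ~75% event; allow 4 binomial SD of simulation error.
  k <- nrow(pat)
  null_tail <- function(r0) 2 * pt(-r0 * sqrt(k - 2) / sqrt(1 - r0^2), k - 2)
  pass_rate <- mean(abs(conc$concordance) >= 0.7)
  expect_lt(pass_rate,
            null_tail(0.7) + 4 * sqrt(null_tail(0.7) * (1 - null_tail(0.7)) / n))
  below_half <- mean(abs(conc$concordance) < 0.5)
  expect_equal(below_half, 1 - null_tail(0.5),
               tolerance = 5 * sqrt(0.25 / n) / (1 - null_tail(0.5)))
})

test_that("candidate classification matches the planted truth", {
  f <- make_roi()
  sc <- screen_genes(f$roi, top_n = 6, n_perm = 50, seed = 2)
  cur <- curate_screen(f$roi, f$em, sc$gene_id[sc$in_union])
  truth <- f$atl$truth
  m <- dplyr::inner_join(cur$candidates, truth, by = "gene_id")
  expect_gt(nrow(m), 0)
  expect_true(all(m$region == m$direction))
  # posterior candidates are called neuroprotective, anterior susceptibility
  expect_true(all(m$candidate_class[m$region == "posterior"] == "neuroprotective"))
  expect_true(all(m$candidate_class[m$region == "anterior"] == "susceptibility"))
  expect_false(any(m$conflict))
})

test_that("the curation filters commute", {
  f <- make_roi()
  pat <- survival_pattern(structure(
    list(annotation = f$atl$annotation, labels = f$atl$labels),
    class = "lobule_map"))
  # detectability first, concordance restricted to its survivors
  det_all <- detectability(f$roi)
  d_first <- det_all$gene_id[det_all$pass_detect]
  conc_after <- pattern_concordance(
    lobule_profiles(f$em, genes = d_first), pat)
  surv1 <- sort(conc_after$gene_id[conc_after$pass_concordance])
  # concordance first, detectability restricted to its survivors
  conc_all <- pattern_concordance(lobule_profiles(f$em), pat)
  c_first <- conc_all$gene_id[conc_all$pass_concordance]
  det_after <- detectability(f$roi, genes = c_first)
  surv2 <- sort(det_after$gene_id[det_after$pass_detect])
  expect_identical(surv1, surv2)
})

test_that("clustering separates planted regions and is deterministic", {
  f <- make_roi()
  planted <- planted_genes(f$atl)
  cl <- cluster_candidates(f$roi, planted)
  ct <- cutree(cl$gene_hclust, k = 2)
  truth <- f$atl$truth$direction[match(planted, f$atl$truth$gene_id)]
  tab <- table(ct, truth)
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_equal(purity, 1)
  # identical rows merge at distance zero
  X <- f$roi
  X$values[2, ] <- X$values[1, ]
  cl2 <- cluster_candidates(X, X$genes[1:3])
  expect_equal(min(cl2$gene_hclust$height), 0)
  # leaf order is reproducible
  cl3 <- cluster_candidates(f$roi, planted)
  expect_identical(cl$gene_order, cl3$gene_order)
  # degenerate single-candidate input
  cl1 <- cluster_candidates(f$roi, planted[1])
  expect_null(cl1$gene_hclust)
  expect_error(write_dendrogram(cl1, tempfile()), "degenerate")
  # newick export round trips through ape
  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, planted)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  # universe of 10 genes, term annotates 5, 3 candidates all annotated
  genes <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(gene_id = genes[1:5], term_id = "T1")
  cand <- genes[1:3]
  res <- enrichment_test(cand, ann, universe = genes)
  expect_equal(res$p, oracle_hyper_enum(k = 3, K = 5, n = 3, N = 10),
               tolerance = 1e-12)
  expect_equal(res$k, 3); expect_equal(res$K, 5); expect_equal(res$N, 10)

  # a term annotating the whole universe is never enriched
  ann2 <- tibble::tibble(gene_id = genes, term_id = "ALL")
  res2 <- enrichment_test(cand, ann2, universe = genes)
  expect_equal(res2$p, 1)

  expect_error(enrichment_test("absent", ann, universe = genes), "universe")
  expect_equal(eval(formals(enrichment_test)$alpha), 0.01)
})
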