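#' SAM relative difference for one gene
#'
#' Computes the Significance Analysis of Microarrays (SAM) statistic for a
#' single gene: `d = (mean(y) - mean(x)) / (s + s0)`, where the gene-specific
#' scatter `s` is the pooled standard deviation scaled by
#' `sqrt(1/n_x + 1/n_y)` and `s0` is the fudge factor that stabilizes `d`
#' for low-variance genes. With `s0 = 0`, `d` equals the pooled-variance
#' Student's t statistic.
#'
#' @param x,y Numeric vectors (>= 2 values each); `y` is the second group so
#'   the sign of `d` matches `mean(y) - mean(x)`.
#' @param s0 Fudge factor, >= 0.
#' @return One-row tibble: `d`, `s`, `r` (raw mean difference). When both
#'   `s` and `s0` are zero with unequal means, `d` is signed infinity.
#' @examples
#' sam_d(c(1, 2, 3), c(4, 5, 7), s0 = 0.1)
#' @export
sam_d <- function(x, y, s0 = 0) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    ls_abort("sam_d needs at least two values per group", "insufficient_replicates")
  }
  if (!is_number(s0) || s0 < 0) ls_abort("s0 must be >= 0", "bad_s0")
  nx <- length(x); ny <- length(y)
  r <- mean(y) - mean(x)
  s <- sqrt(((1 / nx + 1 / ny) / (nx + ny - 2)) *
              (sum((x - mean(x))^2) + sum((y - mean(y))^2)))
  d <- if (s + s0 == 0) {
    if (r == 0) 0 else sign(r) * Inf
  } else r / (s + s0)
  tibble(d = d, s = s, r = r)
}

row_sam_stats <- function(X, idx_a, idx_b, s0) {
  g <- row_group_stats(X, idx_a, idx_b)
  s <- sqrt(((1 / g$na + 1 / g$nb) / (g$na + g$nb - 2)) * (g$ssa + g$ssb))
  r <- g$mb - g$ma
  d <- ifelse(s + s0 == 0, ifelse(r == 0, 0, sign(r) * Inf), r / (s + s0))
  d[!g$tested] <- NA_real_
  list(d = d, s = s, r = r, tested = g$tested)
}

#' Select the SAM fudge factor s0
#'
#' Chooses `s0` from the candidate grid of percentiles 0, 5, ..., 100 of the
#' per-gene scatter `s`, picking the candidate that minimizes the coefficient
#' of variation of the median absolute deviation of `d = r / (s + s0)`
#' across windows of genes grouped by `s` quantiles. This is the standard
#' automatic tuning of the fudge factor: it makes the spread of `d` as
#' uniform as possible across the variance range, so low-variance genes do
#' not dominate the ranking. Deterministic given `s` and `r`.
#'
#' Genes with `s == 0` and `r == 0` (for example all-zero energies in both
#' regions) are excluded before forming quantile windows, since they carry no
#' scatter information and would produce degenerate windows.
#'
#' @param s Per-gene scatter values (from [sam_d()] / the screen).
#' @param r Per-gene raw mean differences.
#' @param n_windows Number of `s`-quantile windows; default 100, reduced for
#'   small gene sets.
#' @return The chosen `s0` (>= 0), with attributes `percentile` (candidate
#'   percentile picked) and `cv_table` (tibble of candidate percentile, s0
#'   and coefficient of variation).
#' @export
choose_s0 <- function(s, r, n_windows = NULL) {
  keep <- is.finite(s) & is.finite(r) & !(s == 0 & r == 0)
  s <- s[keep]; r <- r[keep]
  n <- length(s)
  if (n < 10) {
    inform("choose_s0: fewer than 10 usable genes; falling back to s0 = median(s)")
    out <- median(s)
    attr(out, "percentile") <- 50
    return(out)
  }
  n_windows <- n_windows %||% min(100L, max(2L, n %/% 10L))
  pct <- seq(0, 100, by = 5)
  cand <- quantile(s, pct / 100, names = FALSE, type = 7)
  br <- unique(quantile(s, seq(0, 1, length.out = n_windows + 1), names = FALSE))
  win <- cut(s, br, labels = FALSE, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- vapply(split(d, win), mad, numeric(1))
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) return(Inf)
    sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)
  out <- cand[best]
  attr(out, "percentile") <- pct[best]
  attr(out, "cv_table") <- tibble(percentile = pct, s0 = cand, cv = cv)
  out
}

# all (or B sampled) assignments of n_a of the n voxel columns to group a,
# preserving group sizes ("balanced" label permutations)
sam_permutations <- function(n, n_a, n_perm, max_exact, seed) {
  n_distinct <- choose(n, n_a)
  if (n_distinct <= max_exact || n_distinct <= n_perm) {
    perms <- combn(n, n_a)
    list(perms = perms, exact = TRUE, n_distinct = n_distinct)
  } else {
    perms <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(b) sort(sample.int(n, n_a)),
             integer(n_a))
    })
    list(perms = matrix(perms, nrow = n_a), exact = FALSE,
         n_distinct = n_distinct)
  }
}

# permuted sorted d statistics, one column per permutation. Complete data
# takes a BLAS path (group sums via matrix products); matrices with missing
# values fall back to per-permutation pairwise-exclusion statistics.
perm_d_sorted <- function(X, tested, perms, n_a, s0) {
  B <- ncol(perms)
  nt <- length(tested)
  n_vox <- ncol(X)
  Xt <- X[tested, , drop = FALSE]
  if (!anyNA(Xt)) {
    n_b <- n_vox - n_a
    A <- matrix(0, nrow = n_vox, ncol = B)
    A[cbind(as.vector(perms), rep(seq_len(B), each = n_a))] <- 1
    Sx <- rowSums(Xt)
    Sxx <- rowSums(Xt^2)
    Sa <- Xt %*% A
    Qa <- (Xt^2) %*% A
    ma <- Sa / n_a
    mb <- (Sx - Sa) / n_b
    ssa <- Qa - n_a * ma^2
    ssb <- (Sxx - Qa) - n_b * mb^2
    ssa[ssa < 0] <- 0  # numerical guard
    ssb[ssb < 0] <- 0
    s <- sqrt(((1 / n_a + 1 / n_b) / (n_vox - 2)) * (ssa + ssb))
    D <- (mb - ma) / (s + s0)
    return(apply(D, 2, sort))
  }
  out <- matrix(NA_real_, nrow = nt, ncol = B)
  all_idx <- seq_len(n_vox)
  for (b in seq_len(B)) {
    pa <- perms[, b]
    pb <- setdiff(all_idx, pa)
    out[, b] <- sort(row_sam_stats(X, pa, pb, s0)$d[tested])
  }
  out
}

count_ge <- function(sorted, cut) length(sorted) - findInterval(cut, sorted, left.open = TRUE)
count_le <- function(sorted, cut) findInterval(cut, sorted)

#' Significance Analysis of Microarrays over an ROI contrast
#'
#' Runs the full SAM procedure on the two-group voxel contrast: observed
#' relative differences `d(i)` are sorted and compared with the expected
#' order statistics `d_expected(i)`, the mean over balanced label
#' permutations of the permuted sorted statistics. For a threshold `delta`,
#' asymmetric cutoffs are found where the observed statistic first deviates
#' from the expected by more than `delta`; all genes beyond the cutoffs are
#' called. The false discovery rate at a threshold is the median permuted
#' count of genes beyond the cutoffs divided by the observed count, capped
#' at 1; each gene's `q` is the smallest FDR at which it is called.
#'
#' When the number of distinct balanced permutations is at most `max_exact`
#' (or at most `n_perm`), all of them are enumerated instead of sampled.
#'
#' @param roi An `roi_pair` from [select_roi_pair()], or a plain numeric
#'   matrix (genes x voxels) together with `group`.
#' @param group Two-level factor over the columns (only when `roi` is a
#'   matrix).
#' @param s0 Fudge factor, a number or `"auto"` for [choose_s0()].
#' @param n_perm Number of sampled balanced permutations when exact
#'   enumeration is infeasible.
#' @param delta Optional calling threshold; when given, a `called` column
#'   reports the calls at this threshold.
#' @param seed RNG seed for permutation sampling.
#' @param max_exact Enumerate exactly when the distinct permutation count is
#'   at most this.
#' @return A tibble (class `sam_result`) with one row per gene: `gene_id`,
#'   `d`, `s`, `r`, `d_expected`, `q`, `rank_sam` (descending |d|), `tested`,
#'   and `called` when `delta` was supplied. Attributes: `s0`, `exact`,
#'   `n_perm_used`, `delta_table` (per-candidate-threshold cutoffs, calls,
#'   median false calls and FDR).
#' @export
sam_screen <- function(roi, group = NULL, s0 = "auto", n_perm = 1000,
                       delta = NULL, seed = 1L, max_exact = 10000) {
  if (inherits(roi, "roi_pair")) {
    X <- roi$values
    group <- roi$group
  } else {
    X <- roi
    if (is.null(group)) ls_abort("group is required for a plain matrix", "bad_group")
  }
  group <- as.factor(group)
  if (nlevels(group) != 2L) ls_abort("group must have exactly two levels", "bad_group")
  gene_id <- rownames(X) %||% sprintf("g%05d", seq_len(nrow(X)))
  idx_a <- which(group == levels(group)[1])
  idx_b <- which(group == levels(group)[2])

  pre <- row_sam_stats(X, idx_a, idx_b, 0)
  if (identical(s0, "auto")) {
    s0 <- as.numeric(choose_s0(pre$s[pre$tested], pre$r[pre$tested]))
  }
  if (!is_number(s0) || s0 < 0) ls_abort("s0 must be >= 0 or 'auto'", "bad_s0")
  obs <- row_sam_stats(X, idx_a, idx_b, s0)

  tested <- which(obs$tested & is.finite(obs$d))
  nt <- length(tested)
  if (nt < 2) ls_abort("fewer than 2 testable genes", "insufficient_genes")
  ord <- tested[order(obs$d[tested])]
  dsort <- obs$d[ord]

  n_vox <- ncol(X)
  pm <- sam_permutations(n_vox, length(idx_a), n_perm, max_exact, seed)
  B <- ncol(pm$perms)
  if (!pm$exact && pm$n_distinct < n_perm) {
    inform("sam_screen: permutation space smaller than n_perm; enumerating exactly")
  }
  # sorted permuted d for each balanced relabeling (same s0)
  perm_sorted <- perm_d_sorted(X, tested, pm$perms, length(idx_a), s0)
  d_expected <- rowMeans(perm_sorted)

  dev <- dsort - d_expected
  deltas <- sort(unique(c(0, abs(dev))))
  pos <- dsort > 0
  neg <- dsort < 0
  cut_up <- cut_low <- n_called <- numeric(length(deltas))
  for (t in seq_along(deltas)) {
    up <- which(dev >= deltas[t] & pos)
    cut_up[t] <- if (length(up)) dsort[min(up)] else Inf
    dn <- which(-dev >= deltas[t] & neg)
    cut_low[t] <- if (length(dn)) dsort[max(dn)] else -Inf
    n_called[t] <- sum(dsort >= cut_up[t]) + sum(dsort <= cut_low[t])
  }
  false_counts <- matrix(0, nrow = length(deltas), ncol = B)
  for (b in seq_len(B)) {
    v <- perm_sorted[, b]
    false_counts[, b] <- count_ge(v, cut_up) + count_le(v, cut_low)
  }
  med_false <- apply(false_counts, 1, median)
  fdr <- ifelse(n_called == 0, 0, pmin(1, med_false / n_called))
  delta_table <- tibble(delta = deltas, cut_low = cut_low, cut_up = cut_up,
                        n_called = n_called, median_false = med_false, fdr = fdr)

  # q(i): smallest FDR over thresholds at which gene i is called, then
  # monotonicity (q non-increasing in |d| within each sign) enforced
  qs <- rep(1, nt)
  for (t in seq_along(deltas)) {
    called <- dsort >= cut_up[t] | dsort <= cut_low[t]
    qs[called] <- pmin(qs[called], fdr[t])
  }
  if (any(pos)) {
    ip <- which(pos)  # ascending d; largest |d| last
    qs[ip] <- rev(cummin(rev(qs[ip])))
  }
  if (any(neg)) {
    im <- which(neg)  # ascending d; largest |d| first
    qs[im] <- cummin(qs[im])
  }

  out <- tibble(
    gene_id = gene_id,
    d = obs$d, s = obs$s, r = obs$r,
    d_expected = NA_real_, q = NA_real_,
    tested = obs$tested & is.finite(obs$d)
  )
  out$d_expected[ord] <- d_expected
  out$q[ord] <- qs
  out$rank_sam <- NA_integer_
  rk <- order(-abs(out$d[out$tested]), out$gene_id[out$tested])
  out$rank_sam[which(out$tested)[rk]] <- seq_len(nt)
  if (!is.null(delta)) {
    row <- delta_table[max(which(delta_table$delta <= delta)), ]
    up <- which(dev >= delta & pos)
    cu <- if (length(up)) dsort[min(up)] else Inf
    dn <- which(-dev >= delta & neg)
    cl <- if (length(dn)) dsort[max(dn)] else -Inf
    out$called <- out$tested & (out$d >= cu | out$d <= cl)
  }
  attr(out, "s0") <- s0
  attr(out, "exact") <- pm$exact
  attr(out, "n_perm_used") <- B
  attr(out, "delta_table") <- delta_table
  class(out) <- c("sam_result", class(out))
  out
}

#' Find the SAM threshold targeting a reported FDR
#'
#' @param sam A `sam_result` from [sam_screen()] (or its `delta_table`).
#' @param target_fdr Desired reported FDR, e.g. 0.05.
#' @return One-row tibble: the smallest candidate `delta` whose estimated
#'   FDR is at most `target_fdr`, with its cutoffs, call count and FDR. When
#'   no threshold achieves the target, the largest (most stringent) row.
#' @export
sam_delta_for_fdr <- function(sam, target_fdr = 0.05) {
  dt <- if (is.data.frame(sam) && !is.null(attr(sam, "delta_table"))) {
    attr(sam, "delta_table")
  } else sam
  hit <- which(dt$fdr <= target_fdr)
  if (length(hit) == 0) return(dt[nrow(dt), ])
  dt[min(hit), ]
}

#' Genes called at a SAM threshold
#'
#' @param sam A `sam_result`.
#' @param delta Calling threshold.
#' @return Logical vector over genes (aligned with `sam$gene_id`).
#' @export
sam_calls <- function(sam, delta) {
  tested <- sam$tested
  ok <- sam$d[tested]
  dsort <- sort(ok)
  dexp <- sort(sam$d_expected[tested])
  dev <- dsort - dexp
  pos <- dsort > 0; neg <- dsort < 0
  up <- which(dev >= delta & pos)
  cu <- if (length(up)) dsort[min(up)] else Inf
  dn <- which(-dev >= delta & neg)
  cl <- if (length(dn)) dsort[max(dn)] else -Inf
  tested & (sam$d >= cu | sam$d <= cl)
}
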