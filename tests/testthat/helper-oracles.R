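# Independent oracles. Each recomputes the quantity it checks through a
# different route (base-R model fits, exhaustive enumeration, plain loops)
# so agreement is evidence about the implementation, not a tautology.

# pooled-variance two-sample t via stats::t.test
oracle_t <- function(x, y) {
  ht <- t.test(y, x, var.equal = TRUE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

# scalar SAM statistic evaluated step by step
oracle_sam_d <- function(x, y, s0) {
  nx <- length(x); ny <- length(y)
  r <- mean(y) - mean(x)
  pooled <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  s <- sqrt(pooled) * sqrt(1 / nx + 1 / ny)
  list(d = r / (s + s0), s = s)
}

# full SAM by brute force: every balanced permutation enumerated, every
# quantity recomputed with plain loops over genes
oracle_sam_full <- function(X, idx_a, s0) {
  n <- ncol(X)
  na <- length(idx_a)
  d_of <- function(a_idx) {
    b_idx <- setdiff(seq_len(n), a_idx)
    apply(X, 1, function(x) oracle_sam_d(x[a_idx], x[b_idx], s0)$d)
  }
  d_obs <- d_of(idx_a)
  perms <- combn(n, na)
  Dp <- apply(perms, 2, function(a) sort(d_of(a)))
  dsort <- sort(d_obs)
  dbar <- rowMeans(Dp)
  dev <- dsort - dbar
  deltas <- sort(unique(c(0, abs(dev))))
  q <- rep(1, length(dsort))
  for (del in deltas) {
    up <- which(dev >= del & dsort > 0)
    cu <- if (length(up)) dsort[min(up)] else Inf
    dn <- which(-dev >= del & dsort < 0)
    cl <- if (length(dn)) dsort[max(dn)] else -Inf
    called <- dsort >= cu | dsort <= cl
    nc <- sum(called)
    false_b <- apply(Dp, 2, function(v) sum(v >= cu) + sum(v <= cl))
    fdr <- if (nc == 0) 0 else min(1, median(false_b) / nc)
    q[called] <- pmin(q[called], fdr)
  }
  pos <- which(dsort > 0); neg <- which(dsort < 0)
  if (length(pos)) q[pos] <- rev(cummin(rev(q[pos])))
  if (length(neg)) q[neg] <- cummin(q[neg])
  qq <- numeric(length(d_obs))
  qq[order(d_obs)] <- q
  list(d = d_obs, q = qq, d_expected_sorted = dbar, n_perms = ncol(perms))
}

# grid-search oracle for the fudge factor: recompute the dispersion criterion
# for every candidate with explicit loops and return the argmin
oracle_choose_s0 <- function(s, r, n_windows) {
  pct <- seq(0, 100, by = 5)
  cand <- quantile(s, pct / 100, names = FALSE, type = 7)
  br <- unique(quantile(s, seq(0, 1, length.out = n_windows + 1)))
  win <- cut(s, br, labels = FALSE, include.lowest = TRUE)
  best_cv <- Inf; best <- NA
  for (j in seq_along(cand)) {
    d <- r / (s + cand[j])
    v <- c()
    for (w in sort(unique(win))) v <- c(v, mad(d[win == w]))
    v <- v[is.finite(v)]
    cv <- if (length(v) < 2 || mean(v) == 0) Inf else sd(v) / mean(v)
    if (cv < best_cv) { best_cv <- cv; best <- cand[j] }
  }
  best
}

# hypergeometric upper tail by exhaustive enumeration of candidate sets
oracle_hyper_enum <- function(k, K, n, N) {
  sets <- combn(N, n)
  annotated <- seq_len(K)  # wlog the first K genes carry the term
  hits <- apply(sets, 2, function(sel) sum(sel %in% annotated))
  mean(hits >= k)
}
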