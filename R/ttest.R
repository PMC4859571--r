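#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t statistic with
#' `length(x) + length(y) - 2` degrees of freedom and a two-sided p-value.
#' When both groups have zero variance and equal means the statistic is
#' defined as `t = 0`, `p = 1` (nothing to distinguish); zero variance with
#' unequal means yields a signed infinite statistic and `p = 0`. A Welch
#' (unequal-variance) variant is available behind `var_equal = FALSE`.
#'
#' @param x,y Numeric vectors with at least two finite values each.
#' @param var_equal Pooled-variance Student's t (default) or Welch's t.
#' @return One-row tibble: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @examples
#' student_t(c(1, 2, 3), c(4, 5, 7))
#' @export
student_t <- function(x, y, var_equal = TRUE) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) {
    ls_abort("student_t needs at least two finite values per group",
             "insufficient_replicates")
  }
  nx <- length(x); ny <- length(y)
  mx <- mean(x); my <- mean(y)
  if (var_equal) {
    sp2 <- (sum((x - mx)^2) + sum((y - my)^2)) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    vx <- var(x) / nx; vy <- var(y) / ny
    se <- sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  }
  if (se == 0) {
    t <- if (my == mx) 0 else sign(my - mx) * Inf
  } else {
    t <- (my - mx) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  tibble(t = t, df = df, p = p, mean_x = mx, mean_y = my)
}

# vectorized per-gene two-group moments with pairwise exclusion of missing
# voxels; everything downstream (t, SAM d) derives from these
row_group_stats <- function(X, idx_a, idx_b) {
  Xa <- X[, idx_a, drop = FALSE]
  Xb <- X[, idx_b, drop = FALSE]
  na <- rowSums(!is.na(Xa)); nb <- rowSums(!is.na(Xb))
  ma <- rowMeans(Xa, na.rm = TRUE); mb <- rowMeans(Xb, na.rm = TRUE)
  ssa <- rowSums((Xa - ma)^2, na.rm = TRUE)
  ssb <- rowSums((Xb - mb)^2, na.rm = TRUE)
  list(na = na, nb = nb, ma = ma, mb = mb, ssa = ssa, ssb = ssb,
       tested = na >= 2 & nb >= 2)
}

row_t_stats <- function(X, idx_a, idx_b) {
  g <- row_group_stats(X, idx_a, idx_b)
  df <- g$na + g$nb - 2
  sp2 <- (g$ssa + g$ssb) / df
  se <- sqrt(sp2 * (1 / g$na + 1 / g$nb))
  r <- g$mb - g$ma
  t <- ifelse(se == 0, ifelse(r == 0, 0, sign(r) * Inf), r / se)
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df))
  t[!g$tested] <- NA_real_
  p[!g$tested] <- NA_real_
  tibble(mean_a = g$ma, mean_b = g$mb, n_a = g$na, n_b = g$nb,
         t = t, df = df, p = p, tested = g$tested)
}

#' Bonferroni correction
#'
#' Adjusts p-values for multiple comparisons by multiplying each by the
#' number of tests and capping at 1: `p_adj = min(1, m * p)`. `NA` entries
#' (untested genes) are excluded from the default test count and propagate
#' as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests; defaults to the number of non-missing p-values.
#' @return Vector of adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.5), m = 10)
#' @export
bonferroni <- function(p, m = sum(!is.na(p))) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    ls_abort("p-values must lie in [0, 1]", "bad_pvalues")
  }
  pmin(1, p * m)
}
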