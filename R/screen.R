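#' Flag the top-N genes of each ranking and their union
#'
#' Reproduces the screen's selection rule: the `n` best genes by the t-test
#' (ascending p, ties broken by descending |t| then gene id) and the `n`
#' best by SAM (descending |d|, ties by gene id), and the union of the two
#' lists. The default cutoff is the top 1000 per method. Untested genes are
#' never selected.
#'
#' @param results Data frame with columns `gene_id`, `p`, `t`, `d` (and
#'   optionally `tested`), typically a [screen_genes()] result.
#' @param n Per-method cutoff; default 1000.
#' @return `results` with logical columns `in_top_t`, `in_top_sam`,
#'   `in_union` added (replaced if present).
#' @export
top_n_union <- function(results, n = 1000) {
  stopifnot(is.data.frame(results),
            all(c("gene_id", "p", "t", "d") %in% names(results)))
  if (!is_count(n, min = 1)) ls_abort("n must be a positive integer", "bad_config")
  tested <- if ("tested" %in% names(results)) results$tested else
    !is.na(results$p) & !is.na(results$d)
  kt <- which(tested)
  top_t <- kt[order(results$p[kt], -abs(results$t[kt]), results$gene_id[kt])]
  top_t <- top_t[seq_len(min(n, length(top_t)))]
  top_sam <- kt[order(-abs(results$d[kt]), results$gene_id[kt])]
  top_sam <- top_sam[seq_len(min(n, length(top_sam)))]
  results$in_top_t <- seq_len(nrow(results)) %in% top_t
  results$in_top_sam <- seq_len(nrow(results)) %in% top_sam
  results$in_union <- results$in_top_t | results$in_top_sam
  results
}

#' Per-gene differential expression screen over an ROI contrast
#'
#' Runs both screening statistics over the voxel replicates of the two
#' regions of interest: the pooled-variance Student's t-test with Bonferroni
#' correction (the number of tests is the number of tested genes), and SAM
#' with permutation-estimated FDR. Each gene is ranked under both methods
#' and the top-`top_n` union is flagged. Because same-section voxels are not
#' truly independent replicates, the screen is a prioritization ranking, not
#' calibrated inference on real atlas data; the q-values and adjusted
#' p-values are exact only under the replicate model.
#'
#' @param roi An `roi_pair` from [select_roi_pair()].
#' @param top_n Per-method cutoff for [top_n_union()]; default 1000.
#' @param s0,n_perm,delta,seed,max_exact SAM parameters, see [sam_screen()].
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return A tibble (class `screen_result`), one row per gene: group means
#'   and sizes, `t`, `p`, `p_adj`, `rank_t`, `d`, `s`, `d_expected`, `q`,
#'   `rank_sam`, `tested`, and the top-N flags. SAM attributes (`s0`,
#'   `delta_table`, ...) are carried over.
#' @examples
#' atl <- simulate_atlas(atlas_config(grid_shape = c(20, 8, 8), n_genes = 60,
#'                                    n_posterior = 3, n_anterior = 3, seed = 1))
#' roi <- select_roi_pair(build_expression_matrix(atl))
#' head(screen_genes(roi, top_n = 10, n_perm = 50))
#' @export
screen_genes <- function(roi, top_n = 1000, s0 = "auto", n_perm = 1000,
                         delta = NULL, seed = 1L, max_exact = 10000,
                         welch = FALSE) {
  stopifnot(inherits(roi, "roi_pair"))
  idx_a <- which(roi$group == levels(roi$group)[1])
  idx_b <- which(roi$group == levels(roi$group)[2])
  tt <- row_t_stats(roi$values, idx_a, idx_b)
  if (welch) {
    w <- purrr::map2_dfr(
      seq_along(roi$genes), tt$tested,
      function(i, ok) {
        if (!ok) return(tibble(t = NA_real_, p = NA_real_))
        st <- student_t(roi$values[i, idx_a], roi$values[i, idx_b],
                        var_equal = FALSE)
        tibble(t = st$t, p = st$p)
      })
    tt$t <- w$t; tt$p <- w$p
  }
  sam <- sam_screen(roi, s0 = s0, n_perm = n_perm, delta = delta,
                    seed = seed, max_exact = max_exact)

  out <- tibble(
    gene_id = roi$genes,
    n_a = tt$n_a, n_b = tt$n_b,
    mean_a = tt$mean_a, mean_b = tt$mean_b,
    t = tt$t, p = tt$p,
    p_adj = bonferroni(tt$p),
    d = sam$d, s = sam$s, d_expected = sam$d_expected, q = sam$q,
    tested = tt$tested & sam$tested
  )
  out$rank_t <- NA_integer_
  kt <- which(!is.na(out$p))
  rk <- order(out$p[kt], -abs(out$t[kt]), out$gene_id[kt])
  out$rank_t[kt[rk]] <- seq_along(kt)
  out$rank_sam <- sam$rank_sam
  out <- top_n_union(out, n = top_n)

  attr(out, "s0") <- attr(sam, "s0")
  attr(out, "exact") <- attr(sam, "exact")
  attr(out, "n_perm_used") <- attr(sam, "n_perm_used")
  attr(out, "delta_table") <- attr(sam, "delta_table")
  attr(out, "top_n") <- top_n
  attr(out, "groups") <- levels(roi$group)
  class(out) <- c("screen_result", class(out))
  out
}
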