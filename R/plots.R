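#' SAM quantile plot of a screen result
#'
#' Observed relative differences against their permutation-expected order
#' statistics, the classic SAM diagnostic: genes off the diagonal beyond the
#' calling band are differentially expressed between the regions of
#' interest. Points are colored by membership in the top-N union.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$tested, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_expected, y = .data$d,
                                   colour = .data$in_union)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected relative difference",
                  y = "observed relative difference",
                  colour = "top-N union") +
    ggplot2::theme_minimal()
}

#' Heatmap of the clustered candidate matrix
#'
#' @param clustering A `candidate_clustering` from [cluster_candidates()].
#' @param scale_rows Standardize each gene row before plotting (default
#'   TRUE, the usual heatmap convention).
#' @return A ggplot object.
#' @export
plot_candidate_heatmap <- function(clustering, scale_rows = TRUE) {
  M <- clustering$matrix
  if (scale_rows && nrow(M) > 1) {
    sds <- apply(M, 1, sd)
    sds[sds == 0] <- 1
    M <- (M - rowMeans(M)) / sds
  }
  df <- tibble(
    gene_id = factor(rep(rownames(M), times = ncol(M)), levels = rev(rownames(M))),
    voxel = rep(seq_len(ncol(M)), each = nrow(M)),
    energy = as.vector(M)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$voxel, y = .data$gene_id,
                                   fill = .data$energy)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "ROI voxel (clustered order)", y = NULL,
                  fill = if (scale_rows) "z-score" else "energy") +
    ggplot2::theme_minimal()
}

#' Funnel plot of a screen run
#'
#' Gene counts surviving each stage of the screen, from the full gene set
#' through the top-N union and the curation filters to the final candidate
#' list.
#'
#' @param run A `screen_run` (or a `screen_report`).
#' @return A ggplot object.
#' @export
plot_screen_funnel <- function(run) {
  rep <- if (inherits(run, "screen_run")) run$report else run
  f <- rep$funnel
  f$stage <- factor(f$stage, levels = rev(f$stage))
  ggplot2::ggplot(f, ggplot2::aes(x = .data$count, y = .data$stage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.2,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0, 0.15))) +
    ggplot2::labs(x = "genes", y = NULL) +
    ggplot2::theme_minimal()
}
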