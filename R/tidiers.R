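#' Tidy a screen result
#'
#' @param x A `screen_result` from [screen_genes()].
#' @param ... Unused.
#' @return The per-gene statistics as a plain tibble.
#' @export
tidy.screen_result <- function(x, ...) {
  out <- x
  attributes(out)[c("s0", "exact", "n_perm_used", "delta_table",
                    "top_n", "groups")] <- NULL
  class(out) <- c("tbl_df", "tbl", "data.frame")
  out
}

#' One-row summary of a screen result
#'
#' @param x A `screen_result`.
#' @param ... Unused.
#' @return Tibble with gene counts, the fitted fudge factor and permutation
#'   settings.
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(x$tested),
    n_top_t = sum(x$in_top_t),
    n_top_sam = sum(x$in_top_sam),
    n_union = sum(x$in_union),
    s0 = attr(x, "s0"),
    n_perm = attr(x, "n_perm_used"),
    exact_permutations = attr(x, "exact")
  )
}

#' Tidy a full screen run
#'
#' @param x A `screen_run` from [run_screen()].
#' @param ... Unused.
#' @return The candidate gene table.
#' @export
tidy.screen_run <- function(x, ...) x$candidates

#' One-row summary of a screen run
#'
#' @param x A `screen_run`.
#' @param ... Unused.
#' @return Tibble with the funnel counts spread into columns.
#' @export
glance.screen_run <- function(x, ...) {
  f <- x$report$funnel
  out <- as_tibble(setNames(as.list(f$count), f$stage))
  out$n_posterior <- sum(x$candidates$region == "posterior")
  out$n_anterior <- sum(x$candidates$region == "anterior")
  out
}
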