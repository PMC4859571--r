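#' End-to-end screen configuration
#'
#' Bundles every stage's parameters into one validated object. Defaults
#' encode the screen's printed settings: a 1400 um lateral bound on both
#' regions of interest, the top 1000 genes per method, and an enrichment
#' significance threshold of 0.01. A single global `seed` is fanned out
#' deterministically to the simulation and permutation stages.
#'
#' @param atlas An [atlas_config()] for inline simulation (its seed is
#'   overridden by `seed`).
#' @param roi_a,roi_b [roi_spec()]s of the vulnerable and resistant regions.
#' @param top_n Per-method cutoff of the screen; default 1000.
#' @param s0,n_perm,delta SAM parameters (see [sam_screen()]).
#' @param detect_threshold,detect_min_fraction Detectability filter knobs.
#' @param concordance_min Survival-pattern concordance threshold.
#' @param survival_values Optional named overrides for [survival_pattern()].
#' @param enrichment_alpha Over-representation significance level.
#' @param seed Global RNG seed.
#' @param out_dir Optional output directory for [run_screen()] artifacts.
#' @return A `screen_config`.
#' @export
screen_config <- function(atlas = atlas_config(),
                          roi_a = roi_spec("anterior", c("II", "III")),
                          roi_b = roi_spec("posterior", "X"),
                          top_n = 1000,
                          s0 = "auto",
                          n_perm = 1000,
                          delta = NULL,
                          detect_threshold = 0,
                          detect_min_fraction = 0.1,
                          concordance_min = 0.7,
                          survival_values = NULL,
                          enrichment_alpha = 0.01,
                          seed = 1L,
                          out_dir = NULL) {
  if (!is_count(top_n, min = 1)) ls_abort("top_n must be >= 1", "bad_config")
  atlas$seed <- derive_seed(seed, 0L)
  validate_atlas_config(atlas)
  stopifnot(inherits(roi_a, "roi_spec"), inherits(roi_b, "roi_spec"))
  structure(list(
    atlas = atlas, roi_a = roi_a, roi_b = roi_b,
    top_n = as.integer(top_n), s0 = s0, n_perm = n_perm, delta = delta,
    detect_threshold = detect_threshold,
    detect_min_fraction = detect_min_fraction,
    concordance_min = concordance_min,
    survival_values = survival_values,
    enrichment_alpha = enrichment_alpha,
    seed = as.integer(seed), out_dir = out_dir
  ), class = "screen_config")
}

stage_error <- function(stage, e) {
  ls_abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
           "stage_error")
}

#' Run the full screen: simulate, ingest, screen, curate, report
#'
#' Executes every stage of the pipeline in order on a synthetic atlas (or a
#' supplied one): matrix assembly, ROI contrast, t-test + Bonferroni and SAM
#' screening, top-N union, curation filters, candidate classification,
#' clustering and (optionally) annotation over-representation. Identical
#' configuration and seed give identical outputs.
#'
#' @param config A [screen_config()].
#' @param atlas Optional pre-built `brain_atlas` (skips simulation; the
#'   configured geometry must match).
#' @param annotation Optional gene-term table for [enrichment_test()].
#' @return A `screen_run`: list with `screen` (per-gene statistics tibble),
#'   `candidates`, `detect`, `concordance`, `clustering`, `enrichment`
#'   (NULL without annotation), `report` (a `screen_report`), `truth` (for
#'   synthetic atlases), `roi`, `em`, `config`.
#' @export
run_screen <- function(config, atlas = NULL, annotation = NULL) {
  stopifnot(inherits(config, "screen_config"))
  tryCatch(validate_atlas_config(config$atlas),
           error = function(e) stage_error("configure", e))
  if (is.null(atlas)) {
    atlas <- tryCatch(simulate_atlas(config$atlas),
                      error = function(e) stage_error("simulate", e))
  }
  em <- tryCatch(build_expression_matrix(atlas),
                 error = function(e) stage_error("ingest", e))
  roi <- tryCatch(select_roi_pair(em, config$roi_a, config$roi_b),
                  error = function(e) stage_error("roi", e))
  screen <- tryCatch(
    screen_genes(roi, top_n = config$top_n, s0 = config$s0,
                 n_perm = config$n_perm, delta = config$delta,
                 seed = derive_seed(config$seed, 1L)),
    error = function(e) stage_error("screen", e))

  union_genes <- screen$gene_id[screen$in_union]
  pattern <- tryCatch(
    survival_pattern(structure(list(annotation = atlas$annotation,
                                    labels = atlas$labels),
                               class = "lobule_map"),
                     values = config$survival_values),
    error = function(e) stage_error("pattern", e))
  cur <- tryCatch(
    curate_screen(roi, em, union_genes, pattern = pattern,
                  threshold = config$detect_threshold,
                  min_fraction = config$detect_min_fraction,
                  concordance_min = config$concordance_min,
                  max_lateral_um = config$roi_b$max_lateral_um),
    error = function(e) stage_error("curate", e))
  clustering <- if (nrow(cur$candidates) >= 1) {
    tryCatch(cluster_candidates(roi, cur$candidates$gene_id),
             error = function(e) stage_error("cluster", e))
  } else NULL
  enr <- if (!is.null(annotation)) {
    tryCatch(
      enrichment_test(cur$candidates$gene_id, annotation,
                      universe = screen$gene_id[screen$tested],
                      alpha = config$enrichment_alpha),
      error = function(e) stage_error("enrichment", e))
  } else NULL

  n_detect <- sum(cur$detect$pass_detect)
  passed_detect <- cur$detect$gene_id[cur$detect$pass_detect]
  n_both <- nrow(cur$candidates)
  funnel <- tibble(
    stage = c("genes", "tested", "top_t", "top_sam", "union",
              "post_detectability", "post_concordance", "candidates"),
    count = c(length(screen$gene_id), sum(screen$tested),
              sum(screen$in_top_t), sum(screen$in_top_sam),
              length(union_genes), n_detect,
              n_both, n_both)
  )
  report <- structure(list(
    funnel = funnel,
    by_region = dplyr::count(cur$candidates, .data$region),
    s0 = attr(screen, "s0"),
    n_perm_used = attr(screen, "n_perm_used"),
    exact_permutations = attr(screen, "exact"),
    params = list(
      top_n = config$top_n,
      max_lateral_um_a = config$roi_a$max_lateral_um,
      max_lateral_um_b = config$roi_b$max_lateral_um,
      detect_threshold = config$detect_threshold,
      detect_min_fraction = config$detect_min_fraction,
      concordance_min = config$concordance_min,
      enrichment_alpha = config$enrichment_alpha,
      n_perm = config$n_perm,
      seed = config$seed,
      atlas = config$atlas[setdiff(names(config$atlas), "lobule_map")]
    ),
    package_version = as.character(utils::packageVersion("lobulescreen"))
  ), class = "screen_report")

  run <- structure(list(
    screen = screen, candidates = cur$candidates,
    detect = cur$detect, concordance = cur$concordance,
    clustering = clustering, enrichment = enr,
    report = report, truth = atlas$truth,
    roi = roi, em = em, config = config
  ), class = "screen_run")
  if (!is.null(config$out_dir)) write_screen_run(run, config$out_dir)
  run
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-20s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  }
  if (nrow(x$by_region)) {
    cat("  candidates by region:",
        paste(x$by_region$region, x$by_region$n, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  s0 = %.4g; %d permutations (%s)\n", x$s0, x$n_perm_used,
              if (x$exact_permutations) "exact" else "sampled"))
  invisible(x)
}

#' @export
print.screen_run <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write the artifacts of a screen run
#'
#' Writes the per-gene statistics, candidate table, filter diagnostics,
#' funnel report (JSON) and, when available, the candidate dendrogram
#' (Newick) and reordered heatmap matrix.
#'
#' @param run A `screen_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_screen_run <- function(run, dir) {
  stopifnot(inherits(run, "screen_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(run$screen), file.path(dir, "screen.tsv"))
  readr::write_tsv(run$candidates, file.path(dir, "candidates.tsv"))
  readr::write_tsv(run$detect, file.path(dir, "detectability.tsv"))
  readr::write_tsv(run$concordance, file.path(dir, "concordance.tsv"))
  if (!is.null(run$truth)) readr::write_tsv(run$truth, file.path(dir, "truth.tsv"))
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  }
  rep <- run$report
  rep$funnel <- as.data.frame(rep$funnel)
  rep$by_region <- as.data.frame(rep$by_region)
  jsonlite::write_json(unclass(rep), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(run$clustering) && !is.null(run$clustering$gene_hclust)) {
    write_dendrogram(run$clustering, file.path(dir, "candidates.nwk"))
    hm_mat <- run$clustering$matrix
    colnames(hm_mat) <- paste0("v", run$roi$voxels$voxel[run$clustering$voxel_order])
    hm <- as_tibble(hm_mat, rownames = "gene_id")
    readr::write_tsv(hm, file.path(dir, "heatmap_matrix.tsv"))
  }
  invisible(dir)
}
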