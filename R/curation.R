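#' Detectability filter: expression in exactly one region of interest
#'
#' Formalizes the first curation rule of the screen: keep only genes whose
#' expression is undetectable in one of the two regions of interest, i.e.
#' genes with an absolute expression difference between regions. A gene is
#' "detectable" in an ROI when the fraction of that ROI's voxels with energy
#' strictly above `threshold` is at least `min_fraction`. The defaults
#' (`threshold = 0`, `min_fraction = 0.1`) count any positive energy and
#' demand it in at least 10% of voxels; the original curation was done by
#' eye on hybridization images, so both knobs are exposed.
#'
#' @param roi An `roi_pair`.
#' @param threshold Energy detection threshold (>= 0).
#' @param min_fraction Minimal fraction of ROI voxels above threshold for
#'   detectability (0 < min_fraction <= 1).
#' @param genes Optional subset of gene ids to evaluate.
#' @return Tibble: `gene_id`, `detect_fraction_a`, `detect_fraction_b`,
#'   `detectable_a`, `detectable_b`, `pass_detect` (detectable in exactly
#'   one ROI), `direction` (name of the detectable ROI, `NA` otherwise).
#' @export
detectability <- function(roi, threshold = 0, min_fraction = 0.1, genes = NULL) {
  stopifnot(inherits(roi, "roi_pair"))
  if (!is_number(threshold) || threshold < 0) {
    ls_abort("threshold must be >= 0", "bad_filter")
  }
  if (!is_number(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    ls_abort("min_fraction must lie in (0, 1]", "bad_filter")
  }
  idx <- if (is.null(genes)) seq_along(roi$genes) else match(genes, roi$genes)
  if (anyNA(idx)) ls_abort("unknown gene id in detectability filter", "unknown_gene")
  a <- roi$group == levels(roi$group)[1]
  b <- !a
  X <- roi$values[idx, , drop = FALSE]
  fa <- unname(rowMeans(X[, a, drop = FALSE] > threshold, na.rm = TRUE))
  fb <- unname(rowMeans(X[, b, drop = FALSE] > threshold, na.rm = TRUE))
  da <- fa >= min_fraction
  db <- fb >= min_fraction
  tibble(
    gene_id = roi$genes[idx],
    detect_fraction_a = fa, detect_fraction_b = fb,
    detectable_a = da, detectable_b = db,
    pass_detect = xor(da, db),
    direction = dplyr::case_when(
      da & !db ~ levels(roi$group)[1],
      db & !da ~ levels(roi$group)[2],
      TRUE ~ NA_character_
    )
  )
}

#' Per-gene mean expression profile over lobule segments
#'
#' Averages each gene's energy over the voxels of every lobule segment
#' within the midline band, giving the spatial profile compared against the
#' reference survival pattern.
#'
#' @param em An `expression_matrix`.
#' @param max_lateral_um Lateral bound of the midline band (um).
#' @param genes Optional subset of gene ids.
#' @return Long tibble: `gene_id`, `label`, `mean_energy`.
#' @export
lobule_profiles <- function(em, max_lateral_um = 1400, genes = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  idx <- if (is.null(genes)) seq_along(em$genes) else match(genes, em$genes)
  if (anyNA(idx)) ls_abort("unknown gene id in profile request", "unknown_gene")
  keep <- abs(em$voxels$ml_um) <= max_lateral_um
  labs <- sort(unique(em$voxels$label[keep]))
  prof <- vapply(labs, function(L) {
    cols <- keep & em$voxels$label == L
    rowMeans(em$values[idx, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(length(idx)))
  prof <- matrix(prof, nrow = length(idx), dimnames = list(NULL, labs))
  tibble(
    gene_id = rep(em$genes[idx], times = length(labs)),
    label = rep(labs, each = length(idx)),
    mean_energy = as.vector(prof)
  )
}

#' Concordance of a gene's spatial profile with the survival pattern
#'
#' Second curation rule: keep genes whose expression matches, or is the
#' inverse of, the reference Purkinje cell survival pattern. Each gene's
#' per-segment profile is rescaled to \[0, 1\] and correlated (Pearson) with
#' the reference values; `|score| >= concordance_min` accepts. A positive
#' score means expression follows the survival pattern (candidate
#' neuroprotective), a negative score the inverse (candidate
#' susceptibility). Correlation makes the score invariant to affine
#' rescaling of the profile, so the semi-quantitative energy scale does not
#' matter.
#'
#' @param profiles Long tibble from [lobule_profiles()].
#' @param pattern Tibble from [survival_pattern()].
#' @param concordance_min Acceptance threshold on |score|; default 0.7.
#' @return Tibble: `gene_id`, `concordance`, `scoreable` (FALSE for
#'   zero-variance profiles, which cannot be scored), `pass_concordance`,
#'   `pattern_class` (`"match"`, `"inverse"`, or `NA`).
#' @export
pattern_concordance <- function(profiles, pattern, concordance_min = 0.7) {
  stopifnot(is.data.frame(profiles),
            all(c("gene_id", "label", "mean_energy") %in% names(profiles)),
            all(c("label", "survival") %in% names(pattern)))
  shared <- intersect(unique(profiles$label), pattern$label)
  if (length(shared) < 3) {
    ls_abort("need profile data for at least 3 lobule segments", "bad_profile")
  }
  ref <- pattern$survival[match(shared, pattern$label)]
  wide <- tidyr::pivot_wider(
    dplyr::filter(profiles, .data$label %in% shared),
    id_cols = "gene_id", names_from = "label", values_from = "mean_energy")
  M <- as.matrix(wide[, shared, drop = FALSE])
  score <- apply(M, 1, function(x) {
    ok <- is.finite(x)
    if (sum(ok) < 3) return(NA_real_)
    x <- x[ok]
    rng <- range(x)
    if (rng[1] == rng[2]) return(NA_real_)
    cor((x - rng[1]) / (rng[2] - rng[1]), ref[ok])
  })
  tibble(
    gene_id = wide$gene_id,
    concordance = score,
    scoreable = !is.na(score),
    pass_concordance = !is.na(score) & abs(score) >= concordance_min,
    pattern_class = dplyr::case_when(
      is.na(score) | abs(score) < concordance_min ~ NA_character_,
      score > 0 ~ "match",
      TRUE ~ "inverse"
    )
  )
}

#' Classify candidate neuroprotective and susceptibility genes
#'
#' Combines the two curation filters into the final candidate table. A gene
#' passing both filters is assigned its region of expression from the
#' detectability direction: genes expressed only in the resistant posterior
#' ROI (lobule X) are candidate neuroprotective, genes expressed only in the
#' vulnerable anterior ROI (lobules II/III) candidate susceptibility. Genes
#' whose concordance sign contradicts their region (e.g. posterior
#' expression but inverse-pattern correlation) are kept with a `conflict`
#' flag rather than dropped.
#'
#' @param detect Tibble from [detectability()].
#' @param concordance Tibble from [pattern_concordance()].
#' @param genes Optional gene universe to restrict to (e.g. the top-N
#'   union); defaults to all genes present in both tables.
#' @param region_b Name of the resistant ROI group (direction values equal
#'   to it become region `"posterior"`); default `"posterior"`.
#' @return Tibble of candidates sorted by region then gene id: `gene_id`,
#'   `region`, `candidate_class`, `detect_fraction_a`, `detect_fraction_b`,
#'   `concordance`, `conflict`.
#' @export
classify_candidates <- function(detect, concordance, genes = NULL,
                                region_b = "posterior") {
  joined <- dplyr::inner_join(detect, concordance, by = "gene_id")
  if (!is.null(genes)) joined <- dplyr::filter(joined, .data$gene_id %in% genes)
  out <- joined |>
    dplyr::filter(.data$pass_detect, .data$pass_concordance) |>
    dplyr::mutate(
      region = ifelse(.data$direction == region_b, "posterior", "anterior"),
      candidate_class = ifelse(.data$region == "posterior",
                               "neuroprotective", "susceptibility"),
      conflict = (.data$region == "posterior" & .data$concordance < 0) |
        (.data$region == "anterior" & .data$concordance > 0)
    ) |>
    dplyr::select("gene_id", "region", "candidate_class",
                  "detect_fraction_a", "detect_fraction_b",
                  "concordance", "conflict") |>
    dplyr::arrange(.data$region, .data$gene_id)
  out
}

#' Hierarchical clustering of candidate genes over ROI voxels
#'
#' Agglomerative (average linkage) clustering of the candidate sub-matrix:
#' genes on a correlation distance (1 - Pearson), voxels on Euclidean
#' distance — the standard layout behind expression heatmaps. Deterministic
#' for a given input.
#'
#' @param roi An `roi_pair`.
#' @param genes Character vector of candidate gene ids (>= 1).
#' @return A `candidate_clustering`: list with `genes`, `gene_hclust`,
#'   `voxel_hclust` (NULL when degenerate), `gene_order`, `voxel_order`, and
#'   the reordered `matrix`. With fewer than 2 candidates the output is a
#'   degenerate single-leaf ordering.
#' @export
cluster_candidates <- function(roi, genes) {
  stopifnot(inherits(roi, "roi_pair"))
  idx <- match(genes, roi$genes)
  if (anyNA(idx)) ls_abort("unknown gene id in clustering request", "unknown_gene")
  M <- roi$values[idx, , drop = FALSE]
  rownames(M) <- genes
  if (length(genes) < 2) {
    return(structure(list(genes = genes, gene_hclust = NULL,
                          voxel_hclust = NULL, gene_order = seq_along(genes),
                          voxel_order = seq_len(ncol(M)), matrix = M),
                     class = "candidate_clustering"))
  }
  cm <- suppressWarnings(cor(t(M)))
  cm[!is.finite(cm)] <- 0  # constant rows: no correlation information
  gh <- hclust(as.dist(1 - cm), method = "average")
  vh <- hclust(dist(t(M)), method = "average")
  structure(list(
    genes = genes,
    gene_hclust = gh, voxel_hclust = vh,
    gene_order = gh$order, voxel_order = vh$order,
    matrix = M[gh$order, vh$order, drop = FALSE]
  ), class = "candidate_clustering")
}

#' @export
print.candidate_clustering <- function(x, ...) {
  cat("<candidate_clustering>", length(x$genes), "genes x",
      ncol(x$matrix), "voxels\n")
  invisible(x)
}

#' Export a gene dendrogram as Newick
#'
#' @param clustering A `candidate_clustering` with at least 2 genes.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(clustering, path) {
  if (is.null(clustering$gene_hclust)) {
    ls_abort("degenerate clustering (<2 genes) has no dendrogram", "degenerate")
  }
  ape::write.tree(ape::as.phylo(clustering$gene_hclust), file = path)
  invisible(path)
}

#' Annotation term over-representation among candidates
#'
#' Hypergeometric upper-tail test of each annotation term: the probability
#' of observing at least `k` annotated genes among the `n` candidates drawn
#' from a universe of `N` genes of which `K` carry the term. Matching the
#' screen's stated rule, terms with `p < alpha` (default 0.01) are flagged
#' significant with no multiplicity correction by default; Benjamini-
#' Hochberg adjustment is available behind `adjust = "BH"`.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param annotation Two-column data frame `gene_id`, `term_id` (one row per
#'   gene-term link).
#' @param universe Gene universe; defaults to all genes in `annotation`.
#'   Must contain every candidate.
#' @param alpha Significance threshold on p (default 0.01).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble sorted by p: `term_id`, `k`, `K`, `n`, `N`, `p`,
#'   (`p_adj` when adjusted), `significant`.
#' @export
enrichment_test <- function(candidates, annotation, universe = NULL,
                            alpha = 0.01, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "term_id") %in% names(annotation)))
  universe <- universe %||% unique(annotation$gene_id)
  missing <- setdiff(candidates, universe)
  if (length(missing) > 0) {
    ls_abort(paste0("candidate gene(s) absent from universe: ",
                    paste(head(missing, 5), collapse = ", ")), "bad_universe")
  }
  ann <- dplyr::distinct(
    dplyr::filter(annotation, .data$gene_id %in% universe))
  N <- length(unique(universe))
  n <- length(unique(candidates))
  per_term <- ann |>
    dplyr::group_by(.data$term_id) |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% candidates]),
      .groups = "drop")
  out <- per_term |>
    dplyr::mutate(
      n = n, N = N,
      p = phyper(.data$k - 1, .data$K, N - .data$K, n, lower.tail = FALSE))
  if (adjust == "BH") {
    out$p_adj <- p.adjust(out$p, "BH")
    out$significant <- out$p_adj < alpha
  } else {
    out$significant <- out$p < alpha
  }
  dplyr::arrange(out, .data$p, .data$term_id)
}

#' Run both curation filters and assemble candidates
#'
#' Convenience wrapper chaining [detectability()], [lobule_profiles()] /
#' [pattern_concordance()] and [classify_candidates()] over a gene set
#' (typically the top-N union of the screen). The two filters are
#' conjunctive, so their order does not affect the surviving set.
#'
#' @param roi The `roi_pair` the screen ran on.
#' @param em The full `expression_matrix` (profiles need all lobules).
#' @param genes Gene ids to curate (e.g. `screen$gene_id[screen$in_union]`).
#' @param pattern Survival pattern tibble; default from the matrix's labels.
#' @param threshold,min_fraction Detectability parameters.
#' @param concordance_min Concordance acceptance threshold.
#' @param max_lateral_um Midline band for the profiles.
#' @return List: `detect`, `concordance`, `candidates`.
#' @export
curate_screen <- function(roi, em, genes, pattern = NULL,
                          threshold = 0, min_fraction = 0.1,
                          concordance_min = 0.7, max_lateral_um = 1400) {
  if (is.null(pattern)) {
    segs <- setdiff(unique(em$voxels$label), "background")
    pattern <- tibble(label = segs,
                      survival = unname(default_survival_values[segs]))
    if (anyNA(pattern$survival)) {
      ls_abort("no default survival value for some lobule segments; pass `pattern`",
               "missing_label")
    }
  }
  det <- detectability(roi, threshold = threshold,
                       min_fraction = min_fraction, genes = genes)
  prof <- lobule_profiles(em, max_lateral_um = max_lateral_um, genes = genes)
  conc <- pattern_concordance(prof, pattern, concordance_min = concordance_min)
  cand <- classify_candidates(det, conc, region_b = levels(roi$group)[2])
  list(detect = det, concordance = conc, candidates = cand)
}
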