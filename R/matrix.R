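
voxel_table <- function(annotation, labels, voxel_size_um, origin_um) {
  shape <- dim(annotation)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  tibble(
    voxel = seq_len(prod(shape)),
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    ap_um = origin_um[1] + (idx[, 1] - 1) * voxel_size_um,
    dv_um = origin_um[2] + (idx[, 2] - 1) * voxel_size_um,
    ml_um = origin_um[3] + (idx[, 3] - 1) * voxel_size_um,
    label = labels$label[match(as.vector(annotation), labels$label_id)]
  )
}

#' Assemble the gene x voxel expression matrix
#'
#' Reorganizes per-gene expression volumes into a single matrix whose rows
#' are genes and whose columns are annotated voxels, the central object of
#' the screen: each voxel column is treated downstream as one replicate
#' observation of regional expression. Background-labeled voxels are
#' excluded; genes are ordered lexicographically and voxels in raster order,
#' so the construction is deterministic.
#'
#' @param x A `brain_atlas`, or a list of `expression_volume`s.
#' @param annotation For the volume-list method, a `lobule_map` sharing the
#'   volumes' grid shape.
#' @param ... Unused.
#' @return An `expression_matrix`: list with `values` (genes x voxels),
#'   `genes`, and `voxels` (tibble of voxel index `voxel`, grid indices
#'   `i`,`j`,`k`, physical centre coordinates `ap_um`,`dv_um`,`ml_um` with the
#'   medio-lateral origin at the midline, and `label`).
#' @export
build_expression_matrix <- function(x, ...) UseMethod("build_expression_matrix")

#' @rdname build_expression_matrix
#' @export
build_expression_matrix.brain_atlas <- function(x, ...) {
  vox <- voxel_table(x$annotation, x$labels, x$voxel_size_um, x$origin_um)
  keep <- vox$label != "background"
  if (!any(keep)) ls_abort("no annotated voxels", "no_annotated_voxels")
  ord <- order(x$genes)
  new_expression_matrix(x$energy[ord, keep, drop = FALSE],
                        x$genes[ord], vox[keep, ])
}

#' @rdname build_expression_matrix
#' @export
build_expression_matrix.list <- function(x, annotation, ...) {
  x <- check_volumes(x)
  shape <- dim(x[[1]]$grid)
  if (!identical(as.integer(shape), as.integer(dim(annotation$annotation)))) {
    ls_abort("volume grid shape does not match the annotation volume",
             "shape_mismatch")
  }
  vox <- voxel_table(annotation$annotation, annotation$labels,
                     x[[1]]$voxel_size_um, x[[1]]$origin_um)
  keep <- vox$label != "background"
  if (!any(keep)) ls_abort("no annotated voxels", "no_annotated_voxels")
  genes <- vapply(x, `[[`, character(1), "gene_id")
  values <- do.call(rbind, purrr::map(x, function(v) as.vector(v$grid)[keep]))
  rownames(values) <- genes
  new_expression_matrix(values, genes, vox[keep, ])
}

new_expression_matrix <- function(values, genes, voxels) {
  stopifnot(nrow(values) == length(genes), ncol(values) == nrow(voxels))
  if (anyDuplicated(genes)) ls_abort("duplicate gene_id", "duplicate_gene")
  structure(list(values = values, genes = genes, voxels = voxels),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", length(x$genes), " genes x ", nrow(x$voxels),
      " annotated voxels (", length(unique(x$voxels$label)), " labels)\n", sep = "")
  invisible(x)
}

#' Define a region of interest
#'
#' An ROI is the set of voxels carrying one of the given lobule labels whose
#' centre lies within `max_lateral_um` of the cerebellar midline (inclusive
#' bound on |medio-lateral coordinate|). The default lateral extent is
#' 1400 um.
#'
#' @param name ROI name (used as the group tag downstream).
#' @param labels Character vector of lobule labels, non-empty.
#' @param max_lateral_um Maximal |ML| coordinate of a voxel centre, in um.
#' @return An `roi_spec`.
#' @export
roi_spec <- function(name, labels, max_lateral_um = 1400) {
  if (length(labels) == 0) ls_abort("roi labels must be non-empty", "bad_roi")
  if (!is_number(max_lateral_um) || max_lateral_um <= 0) {
    ls_abort("max_lateral_um must be > 0", "bad_roi")
  }
  structure(list(name = name, labels = unique(labels),
                 max_lateral_um = max_lateral_um), class = "roi_spec")
}

roi_voxels <- function(em, spec) {
  missing <- setdiff(spec$labels, unique(em$voxels$label))
  if (length(missing) == length(spec$labels)) {
    ls_abort(paste0("ROI '", spec$name, "' selects no voxels: label(s) ",
                    paste(spec$labels, collapse = ", "), " absent"), "empty_roi")
  }
  which(em$voxels$label %in% spec$labels &
          abs(em$voxels$ml_um) <= spec$max_lateral_um)
}

#' Select the two-group region-of-interest contrast
#'
#' Extracts the voxel columns of the two regions of interest and tags each
#' with its group, yielding the sub-matrix on which the differential screen
#' runs. Voxels inside one ROI are treated downstream as replicate
#' observations of that region. The default contrast is the vulnerable
#' anterior ROI (lobules II and III) versus the resistant posterior ROI
#' (lobule X), both within 1400 um of the midline.
#'
#' @param em An `expression_matrix`.
#' @param roi_a,roi_b [roi_spec()]s for the two groups (a = vulnerable,
#'   b = resistant).
#' @return An `roi_pair`: list with `values` (genes x selected voxels),
#'   `genes`, `voxels` (selected voxel records with a `group` column of the
#'   ROI names), `group` (factor aligned with the columns), `roi_a`, `roi_b`.
#' @export
select_roi_pair <- function(em,
                            roi_a = roi_spec("anterior", c("II", "III")),
                            roi_b = roi_spec("posterior", "X")) {
  stopifnot(inherits(em, "expression_matrix"))
  ia <- roi_voxels(em, roi_a)
  ib <- roi_voxels(em, roi_b)
  if (length(ia) == 0) ls_abort(paste0("ROI '", roi_a$name, "' is empty after selection"), "empty_roi")
  if (length(ib) == 0) ls_abort(paste0("ROI '", roi_b$name, "' is empty after selection"), "empty_roi")
  if (length(intersect(ia, ib)) > 0) {
    ls_abort("regions of interest overlap: label sets must be disjoint", "roi_overlap")
  }
  sel <- c(ia, ib)
  group <- factor(rep(c(roi_a$name, roi_b$name), c(length(ia), length(ib))),
                  levels = c(roi_a$name, roi_b$name))
  vox <- em$voxels[sel, ]
  vox$group <- group
  structure(list(
    values = em$values[, sel, drop = FALSE],
    genes = em$genes,
    voxels = vox,
    group = group,
    roi_a = roi_a,
    roi_b = roi_b
  ), class = "roi_pair")
}

#' @export
print.roi_pair <- function(x, ...) {
  cat("<roi_pair> ", length(x$genes), " genes; ",
      sum(x$group == levels(x$group)[1]), " '", levels(x$group)[1], "' + ",
      sum(x$group == levels(x$group)[2]), " '", levels(x$group)[2],
      "' voxels\n", sep = "")
  invisible(x)
}
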