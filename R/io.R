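
# On-disk layout. Two interchangeable formats, both plain text:
#   nrrd: volumes/<gene>.nrrd (one dense grid per gene), annotation.nrrd
#   tsv:  energy.tsv (long format gene_id, x, y, z, energy; zero voxels
#         omitted; indices 0-based), annotation.tsv (x, y, z, label_id),
#         meta.tsv (grid shape, voxel size, origin)
# plus, in either case, labels.tsv (label_id, label) and, for synthetic
# atlases, truth.tsv.

#' Write an atlas to disk
#'
#' @param atlas A `brain_atlas`.
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` (long-format table, zero voxels omitted) or
#'   `"nrrd"` (one dense ASCII NRRD volume per gene).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir, format = c("tsv", "nrrd")) {
  stopifnot(inherits(atlas, "brain_atlas"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(atlas$labels, file.path(dir, "labels.tsv"))
  if (!is.null(atlas$truth)) {
    readr::write_tsv(atlas$truth, file.path(dir, "truth.tsv"))
  }
  if (format == "nrrd") {
    vdir <- file.path(dir, "volumes")
    dir.create(vdir, showWarnings = FALSE)
    for (v in as_volumes(atlas)) {
      write_nrrd(v$grid, file.path(vdir, paste0(v$gene_id, ".nrrd")),
                 voxel_size_um = atlas$voxel_size_um, origin_um = atlas$origin_um)
    }
    write_nrrd(atlas$annotation, file.path(dir, "annotation.nrrd"),
               voxel_size_um = atlas$voxel_size_um, origin_um = atlas$origin_um)
  } else {
    long <- as_tibble(atlas)
    readr::write_tsv(long[long$energy != 0, ], file.path(dir, "energy.tsv"))
    shape <- atlas$grid_shape
    idx <- arrayInd(seq_len(prod(shape)), shape)
    readr::write_tsv(
      tibble(x = idx[, 1] - 1L, y = idx[, 2] - 1L, z = idx[, 3] - 1L,
             label_id = as.vector(atlas$annotation)),
      file.path(dir, "annotation.tsv"))
    readr::write_tsv(
      tibble(key = c("nx", "ny", "nz", "voxel_size_um", "ox", "oy", "oz"),
             value = c(shape, atlas$voxel_size_um, atlas$origin_um)),
      file.path(dir, "meta.tsv"))
  }
  invisible(dir)
}

#' Long-format view of an atlas
#'
#' @param x A `brain_atlas`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `x`, `y`, `z` (0-based voxel indices), `energy`.
#' @export
as_tibble.brain_atlas <- function(x, ...) {
  shape <- x$grid_shape
  n_genes <- length(x$genes)
  idx <- arrayInd(seq_len(prod(shape)), shape)
  gene_col <- rep(x$genes, times = prod(shape))
  x_col <- rep(idx[, 1] - 1L, each = n_genes)
  y_col <- rep(idx[, 2] - 1L, each = n_genes)
  z_col <- rep(idx[, 3] - 1L, each = n_genes)
  energy_col <- as.vector(x$energy)
  tibble(gene_id = gene_col, x = x_col, y = y_col, z = z_col,
         energy = energy_col)
}

#' Load per-gene expression volumes
#'
#' Reads either a directory of dense NRRD volumes (`volumes/*.nrrd`) or a
#' long-format TSV (`gene_id`, `x`, `y`, `z`, `energy`; 0-based indices,
#' omitted voxels are zero). Both routes produce identical volumes for the
#' same atlas.
#'
#' @param path Directory containing `volumes/` or the path of a long-format
#'   TSV file (a directory containing `energy.tsv` also works).
#' @param grid_shape,voxel_size_um,origin_um Geometry for the TSV route; read
#'   from `meta.tsv` next to the file when present, otherwise required.
#' @return List of `expression_volume` objects, sorted by gene id.
#' @export
load_volumes <- function(path, grid_shape = NULL, voxel_size_um = NULL,
                         origin_um = NULL) {
  if (dir.exists(path)) {
    vdir <- file.path(path, "volumes")
    if (dir.exists(vdir)) {
      files <- sort(list.files(vdir, pattern = "\\.nrrd$", full.names = TRUE))
      if (length(files) == 0) ls_abort("no volumes found", "no_volumes")
      vols <- purrr::map(files, function(f) {
        nr <- read_nrrd(f)
        structure(list(
          gene_id = sub("\\.nrrd$", "", basename(f)),
          grid = nr$data, voxel_size_um = nr$voxel_size_um,
          origin_um = nr$origin_um
        ), class = "expression_volume")
      })
      return(check_volumes(vols))
    }
    path <- file.path(path, "energy.tsv")
  }
  if (!file.exists(path)) ls_abort("no volumes found", "no_volumes")

  meta_path <- file.path(dirname(path), "meta.tsv")
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
    mv <- setNames(meta$value, meta$key)
    grid_shape <- grid_shape %||% as.integer(mv[c("nx", "ny", "nz")])
    voxel_size_um <- voxel_size_um %||% unname(mv["voxel_size_um"])
    origin_um <- origin_um %||% unname(mv[c("ox", "oy", "oz")])
  }
  if (is.null(grid_shape)) {
    ls_abort("grid_shape is required to read long-format volumes without meta.tsv",
             "bad_volume")
  }
  voxel_size_um <- voxel_size_um %||% 1
  origin_um <- origin_um %||% c(0, 0, 0)

  long <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(gene_id = "c"))
  need <- c("gene_id", "x", "y", "z", "energy")
  if (!all(need %in% names(long))) {
    ls_abort("long-format volume table needs columns gene_id, x, y, z, energy",
             "bad_volume")
  }
  if (nrow(long) == 0) ls_abort("no volumes found", "no_volumes")
  bad <- long$x < 0 | long$y < 0 | long$z < 0 |
    long$x >= grid_shape[1] | long$y >= grid_shape[2] | long$z >= grid_shape[3]
  if (any(bad)) {
    ls_abort("voxel index outside the stated grid shape", "shape_mismatch")
  }
  vols <- purrr::map(split(long, long$gene_id), function(tb) {
    g <- array(0, dim = grid_shape)
    g[cbind(tb$x + 1L, tb$y + 1L, tb$z + 1L)] <- tb$energy
    structure(list(gene_id = tb$gene_id[1], grid = g,
                   voxel_size_um = voxel_size_um, origin_um = origin_um),
              class = "expression_volume")
  })
  check_volumes(unname(vols[order(names(vols))]))
}

check_volumes <- function(vols) {
  ids <- vapply(vols, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) {
    ls_abort(paste0("duplicate gene_id: ", ids[duplicated(ids)][1]), "duplicate_gene")
  }
  shapes <- vapply(vols, function(v) paste(dim(v$grid), collapse = "x"), character(1))
  if (length(unique(shapes)) > 1) {
    ls_abort("volumes have inconsistent grid shapes", "shape_mismatch")
  }
  for (v in vols) {
    if (any(v$grid[!is.na(v$grid)] < 0)) {
      ls_abort(paste0("negative expression energy in ", v$gene_id), "negative_energy")
    }
  }
  vols[order(ids)]
}

#' Read an annotation volume and its label table
#'
#' @param dir Directory written by [write_atlas()].
#' @return A `lobule_map` (annotation array + label tibble).
#' @export
read_annotation_volume <- function(dir) {
  labels <- readr::read_tsv(file.path(dir, "labels.tsv"), show_col_types = FALSE)
  nrrd <- file.path(dir, "annotation.nrrd")
  if (file.exists(nrrd)) {
    ann <- read_nrrd(nrrd)$data
  } else {
    tb <- readr::read_tsv(file.path(dir, "annotation.tsv"), show_col_types = FALSE)
    shape <- c(max(tb$x), max(tb$y), max(tb$z)) + 1L
    ann <- array(NA_integer_, dim = shape)
    ann[cbind(tb$x + 1L, tb$y + 1L, tb$z + 1L)] <- as.integer(tb$label_id)
    if (anyNA(ann)) ls_abort("annotation table does not cover the grid", "bad_volume")
  }
  structure(list(annotation = ann, labels = labels), class = "lobule_map")
}

#' Read an atlas from disk
#'
#' Inverse of [write_atlas()] for either on-disk format.
#'
#' @param dir Directory written by [write_atlas()].
#' @return A `brain_atlas` (with `truth` when `truth.tsv` is present).
#' @export
read_atlas <- function(dir) {
  vols <- load_volumes(dir)
  lm <- read_annotation_volume(dir)
  v1 <- vols[[1]]
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE,
                    col_types = readr::cols(gene_id = "c"))
  } else NULL
  energy <- do.call(rbind, purrr::map(vols, function(v) as.vector(v$grid)))
  genes <- vapply(vols, `[[`, character(1), "gene_id")
  rownames(energy) <- genes
  structure(list(
    energy = energy, genes = genes,
    grid_shape = dim(v1$grid), voxel_size_um = v1$voxel_size_um,
    origin_um = v1$origin_um,
    annotation = lm$annotation, labels = lm$labels,
    truth = truth, config = NULL
  ), class = "brain_atlas")
}
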