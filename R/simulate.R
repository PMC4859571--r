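#' Simulate a volumetric expression-energy atlas with planted ground truth
#'
#' Generates one expression-energy volume per gene under the zero-inflated
#' log-normal noise model described in [atlas_config()], together with the
#' anatomical annotation volume and a `truth` table recording which genes were
#' planted as region-restricted. Planted posterior genes carry positive energy
#' only in voxels labeled lobule X; planted anterior genes only in lobules
#' II/III; null genes draw from the noise model at every voxel. Identical
#' configuration (including seed) yields bit-identical output.
#'
#' @param config An [atlas_config()].
#' @return A `brain_atlas` object: list with
#'   \describe{
#'     \item{energy}{numeric matrix, genes x voxels (all grid voxels, raster
#'       order with the anterior-posterior axis fastest).}
#'     \item{genes}{character vector of gene ids (row order).}
#'     \item{annotation, labels}{the annotation volume and label table.}
#'     \item{truth}{tibble `gene_id`, `direction` (posterior/anterior/null),
#'       `effect_energy`, `expressing_labels`.}
#'     \item{grid_shape, voxel_size_um, origin_um, config}{geometry and
#'       provenance.}
#'   }
#' @examples
#' atl <- simulate_atlas(atlas_config(grid_shape = c(20, 8, 6), n_genes = 50,
#'                                    n_posterior = 2, n_anterior = 2, seed = 7))
#' atl$truth[atl$truth$direction != "null", ]
#' @export
simulate_atlas <- function(config) {
  validate_atlas_config(config)
  lm <- config$lobule_map
  shape <- config$grid_shape
  n_vox <- prod(shape)
  n <- config$n_genes
  labels_of_voxel <- lm$labels$label[match(as.vector(lm$annotation), lm$labels$label_id)]

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  meanlog <- log(config$effect_energy) - sdlog^2 / 2

  gene_id <- sprintf("g%05d", seq_len(n))

  withr::with_seed(config$seed, {
    planted <- sample.int(n, config$n_posterior + config$n_anterior)
    post_idx <- planted[seq_len(config$n_posterior)]
    ant_idx <- setdiff(planted, post_idx)

    energy <- matrix(exp(rnorm(n * n_vox, meanlog, sdlog)), nrow = n)
    if (config$zero_inflation > 0) {
      energy <- energy * (runif(n * n_vox) >= config$zero_inflation)
    }
    if (config$plane_batch_sd > 0) {
      # one multiplicative factor per (gene, sagittal plane): voxels of the
      # same ML plane share a hybridization batch within each gene
      nz <- shape[3]
      fac <- matrix(exp(rnorm(n * nz, 0, config$plane_batch_sd)), nrow = n)
      plane_of_voxel <- rep(seq_len(nz), each = shape[1] * shape[2])
      energy <- energy * fac[, plane_of_voxel, drop = FALSE]
    }
  })

  if (length(post_idx) > 0) {
    energy[post_idx, labels_of_voxel != "X"] <- 0
  }
  if (length(ant_idx) > 0) {
    energy[ant_idx, !(labels_of_voxel %in% c("II", "III"))] <- 0
  }

  direction <- rep("null", n)
  direction[post_idx] <- "posterior"
  direction[ant_idx] <- "anterior"
  truth <- tibble(
    gene_id = gene_id,
    direction = direction,
    effect_energy = ifelse(direction == "null", NA_real_, config$effect_energy),
    expressing_labels = dplyr::case_match(direction,
      "posterior" ~ "X",
      "anterior" ~ "II,III",
      .default = NA_character_
    )
  )

  rownames(energy) <- gene_id
  structure(list(
    energy = energy,
    genes = gene_id,
    grid_shape = shape,
    voxel_size_um = config$voxel_size_um,
    origin_um = config$origin_um,
    annotation = lm$annotation,
    labels = lm$labels,
    truth = truth,
    config = config
  ), class = "brain_atlas")
}

#' @export
print.brain_atlas <- function(x, ...) {
  cat("<brain_atlas> ", length(x$genes), " genes x ",
      paste(x$grid_shape, collapse = " x "), " voxels (",
      x$voxel_size_um, " um)\n", sep = "")
  if (!is.null(x$truth)) {
    tab <- table(x$truth$direction)
    cat("  truth:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract per-gene expression volumes from an atlas
#'
#' @param atlas A `brain_atlas`.
#' @param genes Optional character vector restricting which genes to extract.
#' @return A list of `expression_volume` objects (gene id, 3-D `grid`,
#'   `voxel_size_um`, `origin_um`).
#' @export
as_volumes <- function(atlas, genes = NULL) {
  stopifnot(inherits(atlas, "brain_atlas"))
  genes <- genes %||% atlas$genes
  idx <- match(genes, atlas$genes)
  if (anyNA(idx)) {
    ls_abort(paste0("unknown gene id(s): ",
                    paste(genes[is.na(idx)], collapse = ", ")), "unknown_gene")
  }
  purrr::map2(genes, idx, function(g, i) {
    structure(list(
      gene_id = g,
      grid = array(atlas$energy[i, ], dim = atlas$grid_shape),
      voxel_size_um = atlas$voxel_size_um,
      origin_um = atlas$origin_um
    ), class = "expression_volume")
  })
}

#' @export
print.expression_volume <- function(x, ...) {
  cat("<expression_volume> ", x$gene_id, ": ",
      paste(dim(x$grid), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}
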