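#' Lobule label partition of a voxel grid
#'
#' Builds an axis-aligned block partition of a 3-D voxel grid into cerebellar
#' lobule segments. The first (anterior-posterior) axis is divided, in
#' anatomical order, into lobules II, III, VI, VII, VIII, IX and X, with
#' background margins at both anterior-posterior ends and along the
#' dorsal-ventral borders. The screen only consumes labels, so no attempt is
#' made to model the curved folial geometry of a real cerebellum.
#'
#' @param grid_shape Integer vector of length 3: voxel counts along the
#'   anterior-posterior, dorsal-ventral and medio-lateral axes.
#' @return A `lobule_map` object: a list with `annotation` (3-D integer array
#'   of label ids, 0 = background) and `labels` (tibble with `label_id`,
#'   `label`).
#' @examples
#' lm <- default_lobule_map(c(20, 8, 6))
#' table(lm$labels$label[match(lm$annotation, lm$labels$label_id)])
#' @export
default_lobule_map <- function(grid_shape) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    ls_abort("grid_shape must be three positive voxel counts", "bad_config")
  }
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  lobules <- c("II", "III", "VI", "VII", "VIII", "IX", "X")
  ap_margin <- max(1L, as.integer(round(0.05 * nx)))
  interior <- nx - 2L * ap_margin
  if (interior < length(lobules)) {
    ls_abort(sprintf(
      "grid too shallow along the anterior-posterior axis: %d interior planes for %d lobules",
      interior, length(lobules)), "bad_config")
  }
  # near-equal contiguous AP blocks, one per lobule, in anatomical order
  block <- sort(rep_len(seq_along(lobules), interior))
  ap_label <- c(rep(0L, ap_margin), block, rep(0L, ap_margin))
  dv_margin <- if (ny >= 5L) max(1L, as.integer(round(0.1 * ny))) else 0L
  dv_keep <- rep(TRUE, ny)
  if (dv_margin > 0L) dv_keep[c(seq_len(dv_margin), ny - seq_len(dv_margin) + 1L)] <- FALSE

  ann <- array(0L, dim = grid_shape)
  for (j in seq_len(ny)) {
    if (dv_keep[j]) ann[, j, ] <- ap_label
  }
  labels <- tibble(
    label_id = 0:7,
    label = c("background", lobules)
  )
  structure(list(annotation = ann, labels = labels), class = "lobule_map")
}

#' Synthetic atlas configuration
#'
#' Assembles and validates the parameters of the synthetic expression-energy
#' atlas. The defaults are the study conditions used throughout the package's
#' tests: 2,000 genes on a 40 x 20 x 29 grid of 200 um voxels, with 20 genes
#' restricted to lobule X (posterior, resistant) and 20 restricted to lobules
#' II/III (anterior, vulnerable). Expression energy follows a zero-inflated
#' log-normal model: each voxel of an expressing gene is detected with
#' probability `1 - zero_inflation` and, when detected, carries a log-normal
#' energy with mean `effect_energy` and coefficient of variation `noise_cv`.
#' Null genes draw from the same noise model at every voxel; planted genes are
#' exactly zero outside their expressing lobules.
#'
#' @param grid_shape Voxel counts (anterior-posterior, dorsal-ventral,
#'   medio-lateral).
#' @param voxel_size_um Physical voxel edge length in micrometres.
#' @param lobule_map A `lobule_map` (see [default_lobule_map()]); built from
#'   `grid_shape` when `NULL`.
#' @param n_genes Total number of genes.
#' @param n_posterior Number of planted lobule-X-restricted genes.
#' @param n_anterior Number of planted lobule-II/III-restricted genes.
#' @param effect_energy Mean energy of detected voxels in an expressing
#'   region (arbitrary expression-energy units, > 0).
#' @param zero_inflation Probability that an expressing gene is undetected at
#'   a voxel (in \[0, 1\]).
#' @param noise_cv Coefficient of variation of detected (positive) energies.
#' @param plane_batch_sd Standard deviation, on the log scale, of an optional
#'   shared per-gene, per-sagittal-plane multiplicative batch factor. Emulates
#'   the fact that voxels of one sagittal section derive from the same in situ
#'   hybridization experiment and are therefore not independent. 0 disables.
#' @param origin_um Physical coordinate (um) of the centre of voxel (1,1,1);
#'   the medio-lateral component is 0 at the midline, so the default single
#'   hemisphere starts at the midline plane.
#' @param seed RNG seed used by [simulate_atlas()].
#' @return An `atlas_config` list.
#' @export
atlas_config <- function(grid_shape = c(40L, 20L, 29L),
                         voxel_size_um = 200,
                         lobule_map = NULL,
                         n_genes = 2000L,
                         n_posterior = 20L,
                         n_anterior = 20L,
                         effect_energy = 2,
                         zero_inflation = 0.25,
                         noise_cv = 0.3,
                         plane_batch_sd = 0,
                         origin_um = c(0, 0, 0),
                         seed = 1L) {
  cfg <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_size_um = voxel_size_um,
    lobule_map = lobule_map %||% default_lobule_map(grid_shape),
    n_genes = as.integer(n_genes),
    n_posterior = as.integer(n_posterior),
    n_anterior = as.integer(n_anterior),
    effect_energy = effect_energy,
    zero_inflation = zero_inflation,
    noise_cv = noise_cv,
    plane_batch_sd = plane_batch_sd,
    origin_um = as.numeric(origin_um),
    seed = as.integer(seed)
  ), class = "atlas_config")
  validate_atlas_config(cfg)
  cfg
}

#' Validate an atlas configuration
#'
#' Checks every invariant of the configuration and reports the first one that
#' fails by name.
#'
#' @param config An `atlas_config`.
#' @return `config`, invisibly, if valid.
#' @export
validate_atlas_config <- function(config) {
  if (!inherits(config, "atlas_config")) {
    ls_abort("not an atlas_config object", "bad_config")
  }
  fail <- function(what) ls_abort(paste0("invalid atlas_config: ", what), "bad_config")
  if (length(config$grid_shape) != 3L || any(config$grid_shape < 1L)) {
    fail("grid_shape must be three positive voxel counts")
  }
  if (!is_number(config$voxel_size_um) || config$voxel_size_um <= 0) {
    fail("voxel_size_um must be > 0")
  }
  lm <- config$lobule_map
  if (!inherits(lm, "lobule_map") ||
      !identical(dim(lm$annotation), as.integer(config$grid_shape))) {
    fail("lobule_map annotation must match grid_shape (every voxel exactly one label)")
  }
  if (!all(lm$annotation %in% lm$labels$label_id)) {
    fail("lobule_map contains label ids missing from the label table")
  }
  if (!is_count(config$n_genes)) fail("n_genes must be a non-negative integer")
  if (config$n_genes < 1L) fail("n_genes must be >= 1")
  if (!is_count(config$n_posterior) || !is_count(config$n_anterior)) {
    fail("planted gene counts must be non-negative integers")
  }
  if (config$n_posterior + config$n_anterior > config$n_genes) {
    fail("n_posterior + n_anterior must be <= n_genes")
  }
  if (!is_number(config$effect_energy) || config$effect_energy <= 0) {
    fail("effect_energy must be > 0")
  }
  if (!is_number(config$zero_inflation) ||
      config$zero_inflation < 0 || config$zero_inflation > 1) {
    fail("zero_inflation must lie in [0, 1]")
  }
  if (!is_number(config$noise_cv) || config$noise_cv < 0) {
    fail("noise_cv must be >= 0")
  }
  if (!is_number(config$plane_batch_sd) || config$plane_batch_sd < 0) {
    fail("plane_batch_sd must be >= 0")
  }
  lbl <- lm$labels$label
  needed <- c("II", "III", "X")
  if (!all(needed %in% lbl)) {
    fail("lobule_map must label lobules II, III and X")
  }
  invisible(config)
}

#' @export
print.lobule_map <- function(x, ...) {
  cat("<lobule_map>", paste(dim(x$annotation), collapse = " x "), "voxels;",
      nrow(x$labels), "labels:", paste(x$labels$label, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("<atlas_config>\n")
  cat("  grid: ", paste(x$grid_shape, collapse = " x "),
      " voxels at ", x$voxel_size_um, " um\n", sep = "")
  cat("  genes:", x$n_genes,
      sprintf("(%d posterior + %d anterior planted)\n", x$n_posterior, x$n_anterior))
  cat(sprintf("  energy model: mean %.3g, cv %.3g, zero inflation %.3g, plane batch sd %.3g\n",
              x$effect_energy, x$noise_cv, x$zero_inflation, x$plane_batch_sd))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
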