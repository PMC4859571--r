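test_that("NRRD and long-format TSV round trips reproduce the atlas exactly", {
  atl <- simulate_atlas(tiny_config(n_genes = 8, n_posterior = 1, n_anterior = 1))
  em0 <- build_expression_matrix(atl)

  d_nrrd <- withr::local_tempdir()
  write_atlas(atl, d_nrrd, format = "nrrd")
  back <- read_atlas(d_nrrd)
  expect_equal(back$energy, atl$energy, ignore_attr = TRUE)
  expect_identical(back$annotation, atl$annotation)

  d_tsv <- withr::local_tempdir()
  write_atlas(atl, d_tsv, format = "tsv")
  back2 <- read_atlas(d_tsv)
  expect_equal(back2$energy, atl$energy, ignore_attr = TRUE)

  # both ingestion routes produce identical expression matrices
  em1 <- build_expression_matrix(back)
  em2 <- build_expression_matrix(back2)
  expect_equal(em1$values, em0$values, ignore_attr = TRUE)
  expect_equal(em2$values, em0$values, ignore_attr = TRUE)
  expect_equal(em1$voxels$label, em2$voxels$label)
})

test_that("volume loading rejects malformed inputs by name", {
  empty <- withr::local_tempdir()
  expect_error(load_volumes(empty), "no volumes found")

  tsv <- file.path(withr::local_tempdir(), "energy.tsv")
  readr::write_tsv(tibble::tibble(gene_id = "g1", x = 5, y = 0, z = 0,
                                  energy = 1), tsv)
  expect_error(load_volumes(tsv, grid_shape = c(2, 1, 1)), "outside")
  readr::write_tsv(tibble::tibble(gene_id = "g1", x = 0, y = 0, z = 0,
                                  energy = -2), tsv)
  expect_error(load_volumes(tsv, grid_shape = c(2, 1, 1)), "negative")
})

test_that("a long-format table is transcribed into the dense grid", {
  tsv <- file.path(withr::local_tempdir(), "energy.tsv")
  readr::write_tsv(tibble::tibble(gene_id = c("g1", "g1"),
                                  x = c(0, 1), y = 0, z = 0,
                                  energy = c(0.5, 1.5)), tsv)
  vols <- load_volumes(tsv, grid_shape = c(2, 1, 1))
  expect_length(vols, 1)
  expect_equal(as.vector(vols[[1]]$grid), c(0.5, 1.5))
})

test_that("matrix assembly excludes background and counts voxels correctly", {
  atl <- simulate_atlas(tiny_config(n_genes = 5))
  em <- build_expression_matrix(atl)
  labs <- atl$labels$label[match(as.vector(atl$annotation), atl$labels$label_id)]
  expect_equal(ncol(em$values), sum(labs != "background"))
  expect_equal(nrow(em$values), 5)
  expect_false(any(em$voxels$label == "background"))

  # one gene, two annotated voxels
  ann <- array(0L, c(3, 1, 1)); ann[1:2, 1, 1] <- 7L
  lm <- structure(list(annotation = ann,
                       labels = tibble::tibble(label_id = c(0L, 7L),
                                               label = c("background", "X"))),
                  class = "lobule_map")
  vol <- structure(list(gene_id = "g1", grid = array(c(1, 2, 3), c(3, 1, 1)),
                        voxel_size_um = 200, origin_um = c(0, 0, 0)),
                   class = "expression_volume")
  em1 <- build_expression_matrix(list(vol), lm)
  expect_equal(dim(em1$values), c(1L, 2L))

  # all-background annotation is an error
  lm$annotation[] <- 0L
  expect_error(build_expression_matrix(list(vol), lm), "no annotated voxels")
})

test_that("ROI selection applies the inclusive 1400 um lateral bound", {
  atl <- simulate_atlas(tiny_config(n_genes = 4))  # ML centres 0..1400 um
  em <- build_expression_matrix(atl)
  roi <- select_roi_pair(em)
  # voxel at exactly 1400 um from the midline is included...
  expect_true(any(roi$voxels$ml_um == 1400))
  # ...but a tighter bound excludes it
  roi2 <- select_roi_pair(em, roi_spec("anterior", c("II", "III"), 1300),
                          roi_spec("posterior", "X", 1300))
  expect_false(any(roi2$voxels$ml_um > 1300))
  expect_error(select_roi_pair(em, roi_spec("q", "Q"), roi_spec("posterior", "X")),
               "selects no voxels")
  expect_error(select_roi_pair(em, roi_spec("a", "II"), roi_spec("b", "II")),
               "disjoint")
})

test_that("ROI selection equals a brute-force voxel predicate scan", {
  atl <- simulate_atlas(tiny_config(n_genes = 3))
  em <- build_expression_matrix(atl)
  roi <- select_roi_pair(em)
  brute_a <- em$voxels$voxel[em$voxels$label %in% c("II", "III") &
                               abs(em$voxels$ml_um) <= 1400]
  brute_b <- em$voxels$voxel[em$voxels$label == "X" &
                               abs(em$voxels$ml_um) <= 1400]
  expect_setequal(roi$voxels$voxel[roi$group == "anterior"], brute_a)
  expect_setequal(roi$voxels$voxel[roi$group == "posterior"], brute_b)
  # disjoint and idempotent
  expect_equal(length(intersect(brute_a, brute_b)), 0)
  roi_again <- select_roi_pair(em)
  expect_identical(roi$voxels$voxel, roi_again$voxels$voxel)
})

test_that("mirroring the atlas across the midline preserves ROI voxel counts", {
  atl <- simulate_atlas(tiny_config(n_genes = 3))
  n1 <- table(select_roi_pair(build_expression_matrix(atl))$group)
  nz <- atl$grid_shape[3]
  atl$origin_um[3] <- -(nz - 1) * atl$voxel_size_um  # hemisphere on the other side
  n2 <- table(select_roi_pair(build_expression_matrix(atl))$group)
  expect_equal(as.vector(n1), as.vector(n2))
})
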