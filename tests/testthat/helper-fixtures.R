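# small atlas configurations used across tests; kept deliberately tiny so the
# exhaustive oracles stay fast

tiny_config <- function(n_genes = 60, n_posterior = min(3L, n_genes %/% 6L),
                        n_anterior = min(3L, n_genes %/% 6L), seed = 7, ...) {
  atlas_config(grid_shape = c(20, 8, 8), n_genes = n_genes,
               n_posterior = n_posterior, n_anterior = n_anterior,
               seed = seed, ...)
}

tiny_roi <- function(atlas) {
  select_roi_pair(build_expression_matrix(atlas))
}

# compact all-null atlas at full gene count, used for calibration checks
null_config <- function(seed, n_genes = 2000) {
  atlas_config(grid_shape = c(16, 6, 10), n_genes = n_genes,
               n_posterior = 0, n_anterior = 0, seed = seed)
}

planted_genes <- function(atlas) {
  atlas$truth$gene_id[atlas$truth$direction != "null"]
}
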