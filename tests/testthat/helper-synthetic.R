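# Shared fixture builders; everything is generated in code at test time.

# disjoint synthetic marker panel (no shared genes between clusters)
disjoint_panel <- function(n_clusters = 7, n_markers = 8) {
  stats::setNames(
    lapply(seq_len(n_clusters),
           function(i) sprintf("MRK%02d_%02d", i, seq_len(n_markers))),
    paste0("K", seq_len(n_clusters)))
}

# small well-separated count simulation used across sc tests
small_counts <- function(n_per_cluster = 60, n_clusters = 7, n_genes = 2000,
                         fold = 50, seed = 11, ...) {
  panel <- disjoint_panel(n_clusters)
  spec <- count_sim_spec(
    n_cells_per_cluster = stats::setNames(rep(n_per_cluster, n_clusters),
                                          names(panel)),
    n_genes = n_genes, markers_per_cluster = panel,
    marker_fold_change = fold, seed = seed, ...)
  simulate_counts(spec)
}

# full processing chain with test-sized defaults
process_counts <- function(cm, n_hvg = 1000, n_pc = 15, covariates = NULL) {
  p <- lognormalize(cm)
  p <- scale_regress(p, covariates = covariates, n_hvg = n_hvg)
  run_pca(p, n_pc = n_pc)
}

# count_matrix built from an explicit dense matrix
counts_from_matrix <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  new_count_matrix(m, ...)
}

# processed_matrix wrapping an explicit lognorm matrix (unit tests of
# downstream ops that do not care how normalization happened)
processed_from_lognorm <- function(lognorm, cell_meta = NULL) {
  structure(
    list(lognorm = Matrix::Matrix(lognorm, sparse = TRUE),
         cell_meta = cell_meta %||%
           tibble::tibble(cell_id = colnames(lognorm)),
         scale_factor = 1e4, hvg = NULL, scaled = NULL, pca = NULL),
    class = "processed_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
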