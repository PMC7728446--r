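test_that("degenerate library-size range with exact allocation fixes column sums", {
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 20, B = 20),
                         n_genes = 300, markers_per_cluster = list(),
                         marker_fold_change = 2,
                         library_size_range = c(1000, 1000),
                         exact_library_size = TRUE, seed = 9)
  cm <- simulate_counts(spec)
  expect_true(all(Matrix::colSums(cm$counts) == 1000))
})

test_that("counts are nonnegative integers with aligned metadata", {
  cm <- small_counts(n_per_cluster = 15, n_clusters = 3, n_genes = 300, seed = 2)
  x <- as.matrix(cm$counts)
  expect_true(all(x >= 0))
  expect_true(all(x == round(x)))
  expect_equal(nrow(cm$cell_meta), ncol(cm$counts))
  expect_identical(cm$cell_meta$cell_id, colnames(cm$counts))
  # derived QC columns agree with direct computation
  expect_equal(cm$cell_meta$total_counts, unname(Matrix::colSums(cm$counts)))
  mito <- startsWith(rownames(cm$counts), "MT-")
  expect_equal(cm$cell_meta$mito_fraction,
               unname(Matrix::colSums(cm$counts[mito, ]) /
                        Matrix::colSums(cm$counts)),
               tolerance = 1e-12)
})

test_that("count simulation is bit-identical for a fixed seed", {
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 10, B = 10), n_genes = 200,
                         markers_per_cluster = list(), seed = 33)
  expect_identical(as.matrix(simulate_counts(spec)$counts),
                   as.matrix(simulate_counts(spec)$counts))
})

test_that("too-small gene space is rejected", {
  expect_error(
    count_sim_spec(n_cells_per_cluster = c(A = 5),
                   n_genes = 10,
                   markers_per_cluster = list(A = sprintf("g%d", 1:20))),
    "smaller than")
})

test_that("marker genes are elevated in their planted cluster", {
  cm <- small_counts(n_per_cluster = 40, n_clusters = 3, n_genes = 400,
                     fold = 10, seed = 6)
  panel <- disjoint_panel(3)
  cpm <- sweep(as.matrix(cm$counts), 2, cm$cell_meta$total_counts, "/")
  for (k in names(panel)) {
    in_k <- cm$cell_meta$cluster == k
    for (g in panel[[k]]) {
      expect_gt(mean(cpm[g, in_k]), 2 * mean(cpm[g, !in_k]))
    }
  }
})

test_that("mitochondrial fractions and library sizes stay within their ranges", {
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 60), n_genes = 400,
                         markers_per_cluster = list(),
                         mito_fraction_range = c(0.01, 0.03),
                         library_size_range = c(3000, 3000),
                         exact_library_size = TRUE, seed = 12)
  cm <- simulate_counts(spec)
  # expected fraction is exact by construction; realized fraction is noisy
  expect_true(all(cm$cell_meta$mito_fraction > 0))
  expect_true(all(cm$cell_meta$mito_fraction < 0.08))
  expect_gt(mean(cm$cell_meta$mito_fraction), 0.005)
  expect_lt(mean(cm$cell_meta$mito_fraction), 0.04)
})

test_that("clustering identically-distributed null data is uninformative", {
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 60, B = 60), n_genes = 400,
                         markers_per_cluster = list(), seed = 21)
  cm <- simulate_counts(spec)
  p <- process_counts(cm, n_hvg = 300, n_pc = 10)
  clu <- cluster_cells(p, k = 20, resolution = 0.4, seed = 1)
  ari <- mclust::adjustedRandIndex(clu$cluster, cm$cell_meta$cluster)
  expect_lt(abs(ari), 0.05)
})

test_that("stage labels propagate to cell metadata", {
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 5, B = 5), n_genes = 200,
                         markers_per_cluster = list(),
                         stage_labels = c(A = "E7.0", B = "E7.5"), seed = 1)
  cm <- simulate_counts(spec)
  expect_identical(unique(cm$cell_meta$stage[cm$cell_meta$cluster == "A"]), "E7.0")
  expect_identical(unique(cm$cell_meta$stage[cm$cell_meta$cluster == "B"]), "E7.5")
})
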