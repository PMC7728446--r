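test_that("lognormalize matches its closed form and preserves zeros", {
  m <- matrix(c(10, 0,
                0, 5), 2, 2, byrow = TRUE,
              dimnames = list(c("G1", "G2"), c("c1", "c2")))
  p <- lognormalize(new_count_matrix(m), scale_factor = 1e4)
  # cell c1: single expressed gene holding its whole total
  expect_equal(p$lognorm["G1", "c1"], log(1 + 1e4), tolerance = 1e-12)
  expect_equal(p$lognorm["G2", "c1"], 0)
})

test_that("lognormalize is invariant to doubling a cell's counts", {
  set.seed(4)
  m <- matrix(rpois(200, 2), 20, 10,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("c%02d", 1:10)))
  m[1, colSums(m) == 0] <- 1
  p1 <- lognormalize(new_count_matrix(m))
  p2 <- lognormalize(new_count_matrix(m * 2L))
  expect_equal(as.matrix(p1$lognorm), as.matrix(p2$lognorm), tolerance = 1e-12)
})

test_that("cells with zero totals are rejected at normalization", {
  m <- matrix(c(1, 0), 1, 2, dimnames = list("G1", c("c1", "c2")))
  expect_error(lognormalize(new_count_matrix(m)), "zero total")
})

test_that("lognormalize agrees with the Seurat implementation", {
  set.seed(8)
  m <- matrix(rpois(300, 3), 30, 10,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("c%02d", 1:10)))
  m[1, colSums(m) == 0] <- 1
  ours <- as.matrix(lognormalize(new_count_matrix(m))$lognorm)
  reference <- as.matrix(Seurat::NormalizeData(
    Matrix::Matrix(m, sparse = TRUE), normalization.method = "LogNormalize",
    scale.factor = 1e4, verbose = FALSE))
  expect_equal(ours, reference, tolerance = 1e-10)
})

test_that("HVG selection honours the contract and skips constant genes", {
  cm <- small_counts(n_per_cluster = 30, n_clusters = 3, n_genes = 500, seed = 3)
  p <- lognormalize(cm)
  hvg <- select_hvg(p, n = 200)
  expect_length(hvg, 200)

  # a constant gene (needs constant totals to stay constant after
  # normalization) must never be chosen while others vary
  spec <- count_sim_spec(n_cells_per_cluster = c(A = 40), n_genes = 300,
                         markers_per_cluster = list(),
                         library_size_range = c(2000, 2000),
                         exact_library_size = TRUE, seed = 6)
  cm3 <- simulate_counts(spec)
  m3 <- rbind(as.matrix(cm3$counts), CONST = 10L)
  p3 <- lognormalize(new_count_matrix(m3, cm3$cell_meta))
  hvg3 <- select_hvg(p3, n = nrow(m3) - 1)
  expect_false("CONST" %in% hvg3)
})

test_that("planted high-dispersion genes are recovered in the top set", {
  set.seed(5)
  n_cells <- 200
  # a gene space large enough that the planted genes are a small
  # minority of their mean-expression bin
  base <- matrix(rpois(2000 * n_cells, 2), 2000, n_cells)
  rownames(base) <- sprintf("G%03d", 1:2000)
  # 10 genes switching between 0 and a high value: far higher dispersion
  for (g in 1:10) {
    base[g, ] <- rbinom(n_cells, 1, 0.5) * 40
  }
  colnames(base) <- sprintf("c%03d", seq_len(n_cells))
  p <- lognormalize(new_count_matrix(base))
  hvg <- select_hvg(p, n = 40)
  expect_true(all(sprintf("G%03d", 1:10) %in% hvg))
})

test_that("scaling standardizes rows and regression removes planted effects", {
  cm <- small_counts(n_per_cluster = 50, n_clusters = 2, n_genes = 300, seed = 9)
  p <- lognormalize(cm)

  # pure standardization
  s <- scale_regress(p, covariates = NULL, n_hvg = 100)
  expect_equal(unname(rowMeans(s$scaled)), rep(0, 100), tolerance = 1e-10)
  sds <- apply(s$scaled, 1, sd)
  expect_true(all(abs(sds - 1) < 0.05))   # clipping barely binds

  # a gene exactly linear in a covariate is zeroed by regression
  covar <- p$cell_meta$total_counts
  p2 <- p
  p2$lognorm[5, ] <- 0.001 * covar + 2
  s2 <- scale_regress(p2, covariates = data.frame(tc = covar),
                      genes = rownames(p2$lognorm)[1:50])
  expect_true(all(abs(s2$scaled[5, ]) < 1e-8))

  # planted covariate effect: post-regression correlation is tiny
  set.seed(2)
  noise_gene <- as.numeric(p$lognorm[7, ]) + 0.002 * covar
  p3 <- p
  p3$lognorm[7, ] <- noise_gene
  s3 <- scale_regress(p3, covariates = data.frame(tc = covar),
                      genes = rownames(p3$lognorm)[1:50])
  expect_lt(abs(cor(s3$scaled[7, ], covar)), 0.05)
})

test_that("constant covariates are dropped with a warning", {
  cm <- small_counts(n_per_cluster = 20, n_clusters = 2, n_genes = 200, seed = 2)
  p <- lognormalize(cm)
  expect_warning(
    scale_regress(p, covariates = data.frame(flat = rep(1, ncol(cm$counts))),
                  n_hvg = 50),
    "constant covariate")
})

test_that("PCA is variance-ordered, orthonormal, and improves with rank", {
  # rank-1 data
  set.seed(12)
  u <- rnorm(50); v <- rnorm(80)
  y <- outer(u, v) + matrix(rnorm(50 * 80, 0, 1e-4), 50, 80)
  rownames(y) <- sprintf("G%02d", 1:50); colnames(y) <- sprintf("c%02d", 1:80)
  p <- processed_from_lognorm(abs(y))
  p$scaled <- y
  p <- run_pca(p, n_pc = 5)
  sdev <- attr(p$pca, "sdev")
  expect_gt(sdev[1]^2 / sum(apply(y, 1, stats::var) * (80 - 1) / 80 * 50 / 50), 0)
  expect_gt(sdev[1]^2 / sum(sdev^2), 0.999)

  # orthonormal loadings
  rot <- p$pca_rotation
  expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-8,
               ignore_attr = TRUE)

  # reconstruction error decreases with the number of components
  z <- matrix(rnorm(40 * 60), 40, 60,
              dimnames = list(sprintf("G%02d", 1:40), sprintf("c%02d", 1:60)))
  pz <- processed_from_lognorm(abs(z)); pz$scaled <- z
  errs <- vapply(1:10, function(k) {
    pk <- run_pca(pz, n_pc = k)
    recon <- pk$pca %*% t(pk$pca_rotation)
    sum((t(z) - recon)^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  expect_error(run_pca(pz, n_pc = 100), "exceeds")
})
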