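test_that("mapping a dataset onto itself yields identical embeddings", {
  cm <- small_counts(n_per_cluster = 25, n_clusters = 3, n_genes = 400, seed = 7)
  p <- lognormalize(cm)
  ref <- reference_dataset(p, type_labels = cm$cell_meta$cluster)
  emb <- shared_embedding(p, ref, n_features = 200, n_pc = 10)
  expect_equal(emb$query, emb$ref, tolerance = 1e-8)
})

test_that("disjoint gene universes are rejected", {
  m1 <- matrix(rpois(200, 2), 20, 10,
               dimnames = list(sprintf("AA%02d", 1:20), sprintf("c%02d", 1:10)))
  m2 <- matrix(rpois(200, 2), 20, 10,
               dimnames = list(sprintf("BB%02d", 1:20), sprintf("d%02d", 1:10)))
  m1[1, colSums(m1) == 0] <- 1; m2[1, colSums(m2) == 0] <- 1
  p1 <- lognormalize(new_count_matrix(m1))
  p2 <- lognormalize(new_count_matrix(m2))
  ref <- reference_dataset(p2, type_labels = rep("x", 10))
  expect_error(shared_embedding(p1, ref), "shared features")
})

test_that("an orthology table drives cross-species gene matching", {
  cm <- small_counts(n_per_cluster = 20, n_clusters = 2, n_genes = 300, seed = 3)
  p <- lognormalize(cm)
  # a renamed copy of the same data, linked only via the orthology table
  m2 <- as.matrix(cm$counts)
  rownames(m2) <- paste0("mm-", rownames(m2))
  p2 <- lognormalize(new_count_matrix(m2, cm$cell_meta))
  orth <- data.frame(query_gene = rownames(cm$counts),
                     ref_gene = rownames(m2))
  ref <- reference_dataset(p2, type_labels = cm$cell_meta$cluster)
  emb <- shared_embedding(p, ref, n_features = 200, n_pc = 10,
                          orthology = orth)
  expect_equal(emb$query, emb$ref, tolerance = 1e-8)
})

test_that("nearest reference neighbors fall in the matching cluster", {
  ref_cm <- small_counts(n_per_cluster = 40, n_clusters = 3, n_genes = 500,
                         fold = 20, seed = 11)
  qry_cm <- small_counts(n_per_cluster = 30, n_clusters = 3, n_genes = 500,
                         fold = 20, seed = 99)
  p_ref <- lognormalize(ref_cm); p_qry <- lognormalize(qry_cm)
  ref <- reference_dataset(p_ref, type_labels = ref_cm$cell_meta$cluster)
  emb <- shared_embedding(p_qry, ref, n_features = 300, n_pc = 10)
  sc <- transfer_labels(emb$query, emb$ref, ref$type_labels, k = 1)
  pred <- assign_predicted(sc)
  expect_gte(mean(pred$predicted == qry_cm$cell_meta$cluster), 0.9)
})

test_that("prediction scores are neighbor-label fractions summing to one", {
  # query at the origin; four reference neighbors at known distances
  q <- matrix(c(0, 0), 1, 2, dimnames = list("q1", NULL))
  r <- matrix(c(1, 0, 2, 0, 3, 0, 4, 0), 4, 2, byrow = TRUE,
              dimnames = list(paste0("r", 1:4), NULL))
  sc <- transfer_labels(q, r, c("A", "A", "A", "B"), k = 4,
                        weighting = "uniform")
  expect_equal(unname(sc["q1", "A"]), 0.75)
  expect_equal(unname(sc["q1", "B"]), 0.25)

  # exact duplicate at k = 1 gets the duplicate's label with score 1
  sc1 <- transfer_labels(r[2, , drop = FALSE], r, c("A", "B", "A", "A"), k = 1)
  expect_equal(unname(sc1[1, "B"]), 1)

  # rows always normalize to one under both weightings
  set.seed(5)
  qq <- matrix(rnorm(20), 10, 2); rr <- matrix(rnorm(60), 30, 2)
  labs <- sample(c("x", "y", "z"), 30, replace = TRUE)
  for (wt in c("uniform", "gaussian")) {
    s <- transfer_labels(qq, rr, labs, k = 7, weighting = wt)
    expect_equal(unname(rowSums(s)), rep(1, 10), tolerance = 1e-9)
    expect_true(all(s >= 0))
  }
})

test_that("predicted labels are row argmaxes with lexicographic ties flagged", {
  s <- matrix(c(0.75, 0.25,
                0.5, 0.5,
                0, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("c1", "c2", "c3"), c("L1", "L2")))
  pred <- assign_predicted(s)
  expect_equal(pred$predicted, c("L1", "L1", "L2"))
  expect_equal(pred$tie, c(FALSE, TRUE, FALSE))

  onehot <- diag(3)
  dimnames(onehot) <- list(paste0("c", 1:3), c("A", "B", "C"))
  expect_equal(assign_predicted(onehot)$predicted, c("A", "B", "C"))
})

test_that("composition fractions count correctly and rows sum to one", {
  cl <- rep("k1", 10)
  pred <- c(rep("E7.0", 4), rep("E7.5", 6))
  comp <- composition(cl, pred)
  expect_equal(unname(comp["k1", "E7.0"]), 0.4)
  expect_equal(unname(rowSums(comp)), 1)

  # brute-force cross-tabulation oracle on random labelings
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    cl <- sample(paste0("k", 1:3), n, replace = TRUE)
    pr <- sample(paste0("L", 1:4), n, replace = TRUE)
    comp <- composition(cl, pr)
    for (i in unique(cl)) for (j in unique(pr)) {
      expect_equal(unname(comp[i, j]), sum(cl == i & pr == j) / sum(cl == i))
    }
  }
})

test_that("queries drawn from one stage's distribution recover that stage", {
  stages <- c(K1 = "E6.5", K2 = "E7.0", K3 = "E7.5")
  ref_cm <- simulate_counts(count_sim_spec(
    n_cells_per_cluster = c(K1 = 50, K2 = 50, K3 = 50), n_genes = 500,
    markers_per_cluster = disjoint_panel(3), marker_fold_change = 20,
    stage_labels = stages, seed = 41, gene_mean_seed = 40))
  # query cells drawn from the K2 distribution only, sharing the
  # reference's gene-level parameters
  qry_cm <- simulate_counts(count_sim_spec(
    n_cells_per_cluster = c(K2 = 60), n_genes = 500,
    markers_per_cluster = disjoint_panel(3), marker_fold_change = 20,
    seed = 42, gene_mean_seed = 40))
  p_ref <- lognormalize(ref_cm); p_qry <- lognormalize(qry_cm)
  ref <- reference_dataset(p_ref, type_labels = ref_cm$cell_meta$cluster,
                           stage_labels = "stage")
  emb <- shared_embedding(p_qry, ref, n_features = 300, n_pc = 10)
  sc <- transfer_labels(emb$query, emb$ref, ref$stage_labels, k = 10)
  pred <- assign_predicted(sc)
  expect_gte(mean(pred$predicted == "E7.0"), 0.9)
})

test_that("spearman cluster correlation behaves like ranks", {
  feats <- sprintf("G%02d", 1:4)
  mk_p <- function(vals) {
    # one cell per cluster so averages equal the supplied vectors
    m <- cbind(a = vals[[1]], b = vals[[2]])
    rownames(m) <- feats
    processed_from_lognorm(m)
  }
  a <- mk_p(list(c(1, 2, 3, 4), c(4, 3, 2, 1)))
  # one swapped rank: rho = 1 - 6 * 2 / (4 * 15) = 0.8
  b <- mk_p(list(c(1, 2, 4, 3), c(1, 2, 4, 3)))
  rho <- spearman_cluster_correlation(a, c(a = "A1", b = "A2"),
                                      b, c(a = "B1", b = "B2"), feats)
  expect_equal(unname(rho["A1", "B1"]), 0.8, tolerance = 1e-12)

  # self-correlation and monotone-transform invariance
  cm <- small_counts(n_per_cluster = 20, n_clusters = 3, n_genes = 300, seed = 15)
  p <- lognormalize(cm)
  cl <- cm$cell_meta$cluster
  feats2 <- rownames(cm$counts)[1:50]
  self <- spearman_cluster_correlation(p, cl, p, cl, feats2)
  expect_equal(unname(diag(self)), rep(1, 3), tolerance = 1e-12)

  p_t <- p
  p_t$lognorm <- p$lognorm * 3 + 1   # strictly increasing transform
  trans <- spearman_cluster_correlation(p, cl, p_t, cl, feats2)
  expect_equal(trans, self, tolerance = 1e-12)
})

test_that("constant cluster averages are flagged as NA", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  rownames(m) <- c("G1", "G2", "G3"); colnames(m) <- c("a", "b")
  p <- processed_from_lognorm(m)
  expect_warning(
    rho <- spearman_cluster_correlation(p, c(a = "A", b = "B"),
                                        p, c(a = "A", b = "B"),
                                        c("G1", "G2", "G3")),
    "Constant")
  expect_true(is.na(rho["A", "B"]))
  expect_false(is.na(rho["B", "B"]))
})
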