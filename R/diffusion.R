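# Diffusion maps on a kNN-union Gaussian kernel with density
# normalization, plus cluster-level transition probabilities.

#' Diffusion map of single cells
#'
#' Builds a symmetric k-nearest-neighbor union graph on the cells,
#' weights its edges with a global-width Gaussian kernel
#' \eqn{\exp(-d^2 / (2\sigma^2))}, removes sampling-density bias by
#' normalizing the kernel with the row sums (the alpha = 1
#' normalization), and row-normalizes the result into a cell-to-cell
#' transition matrix. Eigen-decomposition of the transition operator
#' yields the diffusion components; the trivial leading pair
#' (eigenvalue 1, constant eigenvector) is dropped from the returned
#' components. Defaults follow the gastruloid analysis: knn = 40,
#' sigma = 8.
#'
#' @param x A `processed_matrix` with a scaled matrix (cells are
#'   embedded in scaled expression space), or a cells x dims matrix.
#' @param knn Neighbors per cell for the graph.
#' @param sigma Gaussian kernel width (in embedding distance units).
#' @param n_dc Number of nontrivial diffusion components to return.
#' @return A `diffusion_result`: list with `eigenvalues` (descending,
#'   all <= 1), `components` (cells x n_dc), `transition` (row-stochastic
#'   cell x cell matrix), `knn_adjacency` (logical union graph), and
#'   `params`.
#' @export
diffusion_map <- function(x, knn = 40, sigma = 8, n_dc = 20) {
  emb <- if (inherits(x, "processed_matrix")) {
    if (is.null(x$scaled)) abort("Run scale_regress() before diffusion_map().")
    t(x$scaled)
  } else {
    as.matrix(x)
  }
  n <- nrow(emb)
  if (n <= knn) abort("`knn` must be below the number of cells.")
  stop_if_not_scalar_number(sigma, "sigma", min = 1e-9)
  n_dc <- min(as.integer(n_dc), n - 2)

  nn <- knn_indices(emb, knn)
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), each = knn), as.vector(t(nn)))] <- TRUE
  adj <- adj | t(adj)   # kNN union, symmetric

  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  if (comp$no > 1) {
    warn(sprintf("kNN graph has %d connected components; eigenvalue 1 is repeated and components separate them.",
                 comp$no))
  }

  d2 <- as.matrix(stats::dist(emb))^2
  w <- exp(-d2 / (2 * sigma^2))
  w[!adj] <- 0
  diag(w) <- 0
  # density normalization (alpha = 1)
  q <- rowSums(w)
  q[q == 0] <- 1
  w <- w / outer(q, q)
  dd <- rowSums(w)
  dd[dd == 0] <- 1
  trans <- w / dd

  # symmetric conjugate shares eigenvalues with the transition operator
  s <- w / sqrt(outer(dd, dd))
  es <- eigen(s, symmetric = TRUE)
  lambda <- es$values
  phi <- es$vectors / sqrt(dd)        # right eigenvectors of `trans`
  phi <- sweep(phi, 2, sqrt(colSums(phi^2)), "/")
  flip <- apply(phi, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  phi <- sweep(phi, 2, flip, "*")

  ids <- rownames(emb) %||% as.character(seq_len(n))
  dimnames(trans) <- list(ids, ids)
  keep <- seq.int(2, 1 + n_dc)
  components <- phi[, keep, drop = FALSE]
  dimnames(components) <- list(ids, paste0("DC", seq_len(n_dc)))

  structure(
    list(eigenvalues = lambda[keep], components = components,
         transition = trans, knn_adjacency = adj,
         leading_eigenvalue = lambda[1],
         params = list(knn = knn, sigma = sigma, n_dc = n_dc),
         n_components_graph = comp$no),
    class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat(sprintf("<diffusion_result> %d cells, knn = %d, sigma = %g, %d DCs\n",
              nrow(x$transition), x$params$knn, x$params$sigma,
              ncol(x$components)))
  invisible(x)
}

#' Average transition probabilities between clusters
#'
#' Entry (A, B) is the mean, over cells of cluster A, of their total
#' transition probability into cells of cluster B; rows are
#' renormalized and sum to 1.
#'
#' @param d A `diffusion_result`.
#' @param clusters Cluster assignment covering the cells of `d`.
#' @return Clusters x clusters matrix with unit row sums.
#' @export
cluster_transitions <- function(d, clusters) {
  if (!inherits(d, "diffusion_result")) abort("`d` must be a diffusion_result.")
  cl <- as_cluster_factor(clusters, rownames(d$transition))
  levs <- levels(cl)
  out <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  for (b in levs) {
    into_b <- rowSums(d$transition[, cl == b, drop = FALSE])
    for (a in levs) out[a, b] <- mean(into_b[cl == a])
  }
  out / rowSums(out)
}
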