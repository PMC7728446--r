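# Shared-nearest-neighbor graph construction and Louvain clustering.

# k nearest neighbors (excluding self) from a cells x dims embedding;
# exact search on the full distance matrix, fine at desk scale
knn_indices <- function(embedding, k) {
  n <- nrow(embedding)
  if (k >= n) abort(sprintf("`k` (%d) must be below the number of cells (%d).", k, n))
  d <- as.matrix(stats::dist(embedding))
  diag(d) <- Inf
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}

#' Build a shared-nearest-neighbor graph
#'
#' Edges connect cells whose k-nearest-neighbor sets overlap; weights
#' are the Jaccard index of the two neighbor sets (each including the
#' cell itself), and edges below `prune` (default 1/15) are dropped —
#' the construction used by standard single-cell toolkits.
#'
#' @param embedding Cells x dimensions numeric matrix (e.g. the PCA
#'   scores of a `processed_matrix`).
#' @param k Neighbors per cell (default 20).
#' @param prune Jaccard cutoff below which edges are removed.
#' @return An undirected weighted [igraph::igraph] with one vertex per
#'   cell.
#' @export
snn_graph <- function(embedding, k = 20, prune = 1 / 15) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  nn <- knn_indices(embedding, k)
  # neighbor sets include the cell itself, so |union| <= 2(k+1)
  sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  member <- Matrix::sparseMatrix(
    i = unlist(sets), j = rep(seq_len(n), each = k + 1), x = 1,
    dims = c(n, n))
  shared <- as.matrix(Matrix::crossprod(member))   # |intersection|
  jac <- shared / (2 * (k + 1) - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$name <- rownames(embedding) %||% as.character(seq_len(n))
  g
}

#' Cluster cells by Louvain community detection on an SNN graph
#'
#' Builds a Jaccard-weighted shared-nearest-neighbor graph on the
#' embedding and partitions it with Louvain modularity optimization at
#' the given resolution (the defaults used for the gastruloid data:
#' k = 20 neighbors, resolution 0.4). The result is deterministic for a
#' fixed seed.
#'
#' @param x A `processed_matrix` with PCA scores, or a cells x dims
#'   embedding matrix.
#' @param k Neighbors for the SNN graph.
#' @param resolution Louvain resolution parameter.
#' @param prune Jaccard pruning cutoff.
#' @param seed Integer seed.
#' @return Tibble with `cell_id` and `cluster` (factor, labels
#'   `"c1"`, `"c2"`, ... ordered by decreasing size).
#' @export
cluster_cells <- function(x, k = 20, resolution = 0.4, prune = 1 / 15,
                          seed = 1L) {
  embedding <- if (inherits(x, "processed_matrix")) {
    if (is.null(x$pca)) abort("Run run_pca() before cluster_cells().")
    x$pca
  } else {
    as.matrix(x)
  }
  stop_if_not_scalar_number(resolution, "resolution", min = 0)
  g <- snn_graph(embedding, k = k, prune = prune)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  membership <- igraph::membership(comm)

  sizes <- sort(table(membership), decreasing = TRUE)
  relabel <- setNames(paste0("c", seq_along(sizes)), names(sizes))
  tibble(cell_id = igraph::V(g)$name,
         cluster = factor(relabel[as.character(membership)],
                          levels = unname(relabel)))
}

# normalize the many accepted cluster inputs to a named factor
as_cluster_factor <- function(clusters, cell_ids = NULL) {
  if (is.data.frame(clusters)) {
    if (!all(c("cell_id", "cluster") %in% names(clusters))) {
      abort("Cluster tables need `cell_id` and `cluster` columns.")
    }
    f <- factor(clusters$cluster)
    names(f) <- clusters$cell_id
  } else {
    f <- factor(clusters)
    if (!is.null(names(clusters))) names(f) <- names(clusters)
  }
  if (!is.null(cell_ids)) {
    if (is.null(names(f))) {
      if (length(f) != length(cell_ids)) {
        abort("Cluster labels do not match the cell universe.")
      }
      names(f) <- cell_ids
    } else {
      if (!all(cell_ids %in% names(f))) {
        abort("Cluster labels missing for some cells.")
      }
      f <- f[cell_ids]
    }
  }
  droplevels(f)
}
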