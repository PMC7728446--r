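# Cluster x predicted-label composition tables and the randomization
# significance test for transferred labels.

# align cluster and predicted labels over one cell universe
align_cluster_predicted <- function(clusters, predicted) {
  if (is.data.frame(predicted)) {
    if (!all(c("cell_id", "predicted") %in% names(predicted))) {
      abort("`predicted` tables need `cell_id` and `predicted` columns.")
    }
    pv <- setNames(as.character(predicted$predicted), predicted$cell_id)
  } else {
    pv <- as.character(predicted)
    if (!is.null(names(predicted))) names(pv) <- names(predicted)
  }
  cl <- as_cluster_factor(clusters)
  if (length(cl) == 0) abort("Empty cell universe.")
  if (!is.null(names(cl)) && !is.null(names(pv))) {
    if (!setequal(names(cl), names(pv))) {
      abort("Clusters and predictions must cover the same cells.")
    }
    pv <- pv[names(cl)]
  } else if (length(cl) != length(pv)) {
    abort("Clusters and predictions must cover the same cells.")
  }
  list(cluster = cl, predicted = factor(pv, levels = sort(unique(pv))))
}

#' Composition of predicted labels within each cluster
#'
#' Cross-tabulates query clusters against predicted (transferred)
#' labels and converts counts to per-cluster fractions, the
#' `Perc` statistic resampled by [permutation_significance()]. Every
#' row sums to 1.
#'
#' @param clusters Cluster assignment ([cluster_cells()] tibble or
#'   (named) vector).
#' @param predicted Predicted labels ([assign_predicted()] tibble or
#'   (named) vector) over the same cells.
#' @return A `composition_table`: clusters x labels matrix of fractions.
#' @export
composition <- function(clusters, predicted) {
  al <- align_cluster_predicted(clusters, predicted)
  tab <- table(cluster = al$cluster, label = al$predicted)
  if (any(rowSums(tab) == 0)) abort("Empty cluster in composition table.")
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  structure(frac, class = c("composition_table", "matrix"))
}

#' Randomization test for transferred-label composition
#'
#' Tests, for every (cluster, label) pair, whether a transferred label
#' is over-represented in a cluster relative to chance. For each
#' cluster of size \eqn{n_i}, `B` resamples of \eqn{n_i} cells are
#' drawn with replacement from all query cells; the label composition
#' \eqn{Perc_{ijk}} of each resample forms the background
#' distribution, and
#' \deqn{p_{ij} = \frac{\#\{k : Perc_{ijk} \ge Perc_{ij}\} + 1}{B + 1},}
#' where the pseudo-count of 1 avoids p-values of 0. Labels are called
#' significant at `p <= alpha` with no multiple-testing correction,
#' which is recorded in the result.
#'
#' One seed governs the whole resample stream: clusters are processed
#' in order of first appearance in the cell sequence (so renaming or
#' reordering cluster labels permutes the result without changing any
#' draw) and each cluster consumes `B` resamples in sequence, making
#' results reproducible bit for bit.
#'
#' @param clusters,predicted As in [composition()].
#' @param B Number of resamples (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return A `permutation_result`: list with `observed`
#'   (composition table), `p_values`, `significant`, `B`, `alpha`,
#'   `seed`.
#' @export
permutation_significance <- function(clusters, predicted, B = 1000,
                                     alpha = 0.05, seed = 1L) {
  stop_if_not_scalar_number(B, "B", min = 1)
  stop_if_not_scalar_number(alpha, "alpha", min = 0, max = 1)
  al <- align_cluster_predicted(clusters, predicted)
  observed <- composition(al$cluster, al$predicted)
  n <- length(al$predicted)
  labels <- levels(al$predicted)
  pred_int <- as.integer(al$predicted)
  B <- as.integer(B)

  p_values <- matrix(NA_real_, nrow(observed), ncol(observed),
                     dimnames = dimnames(observed))
  set.seed(as.integer(seed))
  for (i in unique(as.character(al$cluster))) {
    n_i <- sum(al$cluster == i)
    if (n_i == 0) abort(sprintf("Cluster '%s' is empty.", i))
    # one vector draw consumes the stream exactly like B successive
    # sample() calls of size n_i; rows are the resamples
    draws <- matrix(sample.int(n, B * n_i, replace = TRUE),
                    nrow = B, byrow = TRUE)
    drawn_labels <- matrix(pred_int[draws], nrow = B)
    for (j in seq_along(labels)) {
      perc_k <- rowMeans(drawn_labels == j)
      p_values[i, j] <- (sum(perc_k >= observed[i, j]) + 1) / (B + 1)
    }
  }

  structure(
    list(observed = observed, p_values = p_values,
         significant = p_values <= alpha,
         B = B, alpha = alpha, seed = as.integer(seed),
         multiple_testing = "none (alpha applied per pair)"),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d clusters x %d labels, B = %d, alpha = %g; %d significant pair(s)\n",
    nrow(x$p_values), ncol(x$p_values), x$B, x$alpha, sum(x$significant)))
  invisible(x)
}

#' Spearman correlation between cluster-average expression profiles
#'
#' Averages log-normalized expression over the cells of each cluster on
#' both sides, restricted to a shared feature list (typically the top
#' shared highly variable genes), and rank-correlates every cluster
#' pair. Being rank-based, the result is invariant to strictly
#' increasing transforms of either side. Cluster averages that are
#' constant across features have undefined correlation; those entries
#' are returned as `NA` with a warning.
#'
#' @param a,b `processed_matrix` objects.
#' @param clusters_a,clusters_b Cluster assignments for each side.
#' @param features Character vector of shared feature names (>= 3).
#' @return Matrix of Spearman rho, clusters of `a` x clusters of `b`.
#' @export
spearman_cluster_correlation <- function(a, clusters_a, b, clusters_b,
                                         features) {
  if (!inherits(a, "processed_matrix") || !inherits(b, "processed_matrix")) {
    abort("`a` and `b` must be processed_matrix objects.")
  }
  features <- unique(features)
  if (length(features) < 3) abort("Need at least 3 shared features.")
  for (side in list(a, b)) {
    if (!all(features %in% rownames(side$lognorm))) {
      abort("All `features` must be present in both matrices.")
    }
  }
  avg <- function(p, cl) {
    f <- as_cluster_factor(cl, colnames(p$lognorm))
    m <- as.matrix(p$lognorm[features, , drop = FALSE])
    vapply(levels(f), function(k) rowMeans(m[, f == k, drop = FALSE]),
           numeric(length(features)))
  }
  ma <- avg(a, clusters_a); mb <- avg(b, clusters_b)
  const_a <- apply(ma, 2, function(v) sd(v) == 0)
  const_b <- apply(mb, 2, function(v) sd(v) == 0)
  if (any(const_a) || any(const_b)) {
    warn("Constant cluster-average profile(s); correlations reported as NA.")
  }
  rho <- suppressWarnings(cor(ma, mb, method = "spearman"))
  rho[const_a, ] <- NA_real_
  rho[, const_b] <- NA_real_
  rho
}
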