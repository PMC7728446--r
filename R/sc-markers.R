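# One-vs-rest Wilcoxon rank-sum marker detection with the standard
# log-fold-change and detection-rate thresholds.

# vectorized two-sided rank-sum test (normal approximation with tie
# correction and continuity correction) of group vs rest for each row
rank_sum_rows <- function(y, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  p <- numeric(nrow(y))
  for (g in seq_len(nrow(y))) {
    r <- rank(y[g, ])
    w <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(y[g, ])
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
    if (sigma2 <= 0) { p[g] <- 1; next }
    mu <- n1 * n2 / 2
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p[g] <- 2 * pnorm(-abs(z))
  }
  pmin(p, 1)
}

#' Find cluster marker genes
#'
#' For every cluster, compares each gene's log-normalized expression in
#' the cluster against all other cells with a two-sided Wilcoxon
#' rank-sum test, reporting the natural-log fold change of
#' `mean(expm1(x)) + 1` ratios, in/out detection fractions, and
#' Bonferroni-adjusted p-values. Genes are tested (and reported) only
#' when the absolute log fold change is at least `min_logfc` and the
#' detection fraction in at least one of the two populations reaches
#' `min_detection` — the 0.25 / 25% convention. Singleton clusters are
#' skipped with a warning.
#'
#' @param p A `processed_matrix`.
#' @param clusters Output of [cluster_cells()], or a (named) vector of
#'   cluster labels.
#' @param min_logfc Minimum absolute log fold change (default 0.25).
#' @param min_detection Minimum detection fraction in either population
#'   (default 0.25).
#' @param alpha Significance level on the adjusted p-value; rows above
#'   it are dropped. Use 1 to keep everything passing the effect-size
#'   filters.
#' @return Tibble with `cluster`, `gene`, `avg_logFC`, `pct_in`,
#'   `pct_out`, `p_value`, `p_adj`, sorted by cluster then `p_adj`.
#' @export
find_markers <- function(p, clusters, min_logfc = 0.25,
                         min_detection = 0.25, alpha = 0.05) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  cl <- as_cluster_factor(clusters, colnames(p$lognorm))
  if (nlevels(cl) < 2) abort("Need at least two clusters.")
  y <- as.matrix(p$lognorm)
  n_genes <- nrow(y)
  expd <- expm1(y)
  det <- y > 0

  out <- list()
  for (k in levels(cl)) {
    in_k <- cl == k
    if (sum(in_k) < 2) {
      warn(sprintf("Cluster '%s' is a singleton; skipped.", k))
      next
    }
    mean_in <- rowMeans(expd[, in_k, drop = FALSE])
    mean_out <- rowMeans(expd[, !in_k, drop = FALSE])
    logfc <- log(mean_in + 1) - log(mean_out + 1)
    pct_in <- rowMeans(det[, in_k, drop = FALSE])
    pct_out <- rowMeans(det[, !in_k, drop = FALSE])
    pass <- abs(logfc) >= min_logfc & pmax(pct_in, pct_out) >= min_detection
    if (!any(pass)) next
    pv <- rank_sum_rows(y[pass, , drop = FALSE], in_k)
    padj <- pmin(pv * n_genes, 1)   # Bonferroni over all genes
    tab <- tibble(cluster = k, gene = rownames(y)[pass],
                  avg_logFC = logfc[pass], pct_in = pct_in[pass],
                  pct_out = pct_out[pass], p_value = pv, p_adj = padj)
    out[[k]] <- tab[tab$p_adj <= alpha, , drop = FALSE]
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(cluster = character(0), gene = character(0),
                  avg_logFC = numeric(0), pct_in = numeric(0),
                  pct_out = numeric(0), p_value = numeric(0),
                  p_adj = numeric(0)))
  }
  dplyr::arrange(res, .data$cluster, .data$p_adj, dplyr::desc(.data$avg_logFC))
}
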