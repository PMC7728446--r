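# Query-onto-reference mapping: shared PCA embedding and
# nearest-neighbor label transfer with prediction scores.

#' Bundle a processed matrix with reference labels
#'
#' @param p A `processed_matrix` for the reference cells.
#' @param type_labels Per-cell cell-type labels (vector, or `cell_meta`
#'   column name).
#' @param stage_labels Optional per-cell stage labels (vector or column
#'   name).
#' @return A `reference_dataset`.
#' @export
reference_dataset <- function(p, type_labels, stage_labels = NULL) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  grab <- function(lab) {
    if (is.null(lab)) return(NULL)
    if (is.character(lab) && length(lab) == 1 && lab %in% names(p$cell_meta)) {
      lab <- p$cell_meta[[lab]]
    }
    if (length(lab) != ncol(p$lognorm)) {
      abort("Labels must cover every reference cell.")
    }
    as.character(lab)
  }
  structure(list(matrix = p, type_labels = grab(type_labels),
                 stage_labels = grab(stage_labels)),
            class = "reference_dataset")
}

# harmonize gene identifiers: optional two-column orthology table
# (query_gene, ref_gene), default case-insensitive symbol matching
match_genes <- function(query_genes, ref_genes, orthology = NULL) {
  if (is.null(orthology)) {
    qk <- toupper(query_genes); rk <- toupper(ref_genes)
    shared <- intersect(qk, rk)
    tibble(query_gene = query_genes[match(shared, qk)],
           ref_gene = ref_genes[match(shared, rk)])
  } else {
    orthology <- as.data.frame(orthology)[, 1:2]
    names(orthology) <- c("query_gene", "ref_gene")
    keep <- orthology$query_gene %in% query_genes &
      orthology$ref_gene %in% ref_genes
    orthology <- orthology[keep, , drop = FALSE]
    orthology[!duplicated(orthology$query_gene) &
                !duplicated(orthology$ref_gene), , drop = FALSE]
    as_tibble(orthology[!duplicated(orthology$query_gene), , drop = FALSE])
  }
}

#' Embed query and reference cells in a common PCA space
#'
#' Harmonizes gene identifiers (case-insensitive symbols, or an
#' explicit two-column orthology table for cross-species runs), takes
#' the reference's highly variable genes among the shared features,
#' standardizes each dataset per gene within itself, fits PCA on the
#' reference, and projects both datasets with the reference loadings.
#'
#' @param query A `processed_matrix`.
#' @param ref A [reference_dataset()].
#' @param n_features Number of shared reference-HVG features to use.
#' @param n_pc Number of principal components.
#' @param orthology Optional data.frame `(query_gene, ref_gene)`.
#' @return List with `query` and `ref` (cells x n_pc score matrices),
#'   plus `features` (the gene-pair tibble used).
#' @export
shared_embedding <- function(query, ref, n_features = 2000, n_pc = 30,
                             orthology = NULL) {
  if (!inherits(query, "processed_matrix")) abort("`query` must be a processed_matrix.")
  if (!inherits(ref, "reference_dataset")) abort("`ref` must be a reference_dataset.")
  pairs <- match_genes(rownames(query$lognorm), rownames(ref$matrix$lognorm),
                       orthology)
  if (nrow(pairs) < 50) {
    abort(sprintf("Only %d shared features after harmonization (need >= 50).",
                  nrow(pairs)))
  }
  ref_hvg <- select_hvg(ref$matrix, n = nrow(ref$matrix$lognorm))
  ranked <- pairs[order(match(pairs$ref_gene, ref_hvg)), , drop = FALSE]
  use <- head(ranked, n_features)

  # both datasets are standardized with the reference's per-gene moments,
  # so a query with skewed composition still lands on the right part of
  # the reference manifold
  ref_raw <- as.matrix(ref$matrix$lognorm[use$ref_gene, , drop = FALSE])
  qry_raw <- as.matrix(query$lognorm[use$query_gene, , drop = FALSE])
  mu <- rowMeans(ref_raw)
  s <- apply(ref_raw, 1, sd)
  s <- ifelse(s > 0, s, 1)
  ref_z <- (ref_raw - mu) / s
  qry_z <- (qry_raw - mu) / s

  n_pc <- min(n_pc, ncol(ref_z) - 1, nrow(ref_z))
  pc <- prcomp(t(ref_z), center = FALSE, scale. = FALSE, rank. = n_pc)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  ref_emb <- sweep(pc$x, 2, flip, "*")
  rownames(ref_emb) <- colnames(ref_z)
  qry_emb <- t(qry_z) %*% rot
  rownames(qry_emb) <- colnames(qry_z)
  list(query = qry_emb, ref = ref_emb, features = use)
}

#' Transfer reference labels to query cells as prediction scores
#'
#' For each query cell, finds its `k` nearest reference cells in the
#' shared embedding and scores each reference label by the (weighted)
#' fraction of neighbors carrying it. Gaussian weighting uses a
#' per-cell bandwidth equal to the distance to the k-th neighbor;
#' uniform weighting gives each neighbor weight 1/k. Every row of the
#' returned score matrix sums to 1.
#'
#' @param query_emb,ref_emb Cells x dims matrices from
#'   [shared_embedding()] (or any common embedding).
#' @param labels Per-reference-cell labels.
#' @param k Number of neighbors (default 30, capped at the reference
#'   size).
#' @param weighting `"gaussian"` (default) or `"uniform"`.
#' @return A `prediction_scores` matrix, query cells x reference labels.
#' @export
transfer_labels <- function(query_emb, ref_emb, labels, k = 30,
                            weighting = c("gaussian", "uniform")) {
  weighting <- match.arg(weighting)
  query_emb <- as.matrix(query_emb); ref_emb <- as.matrix(ref_emb)
  if (ncol(query_emb) != ncol(ref_emb)) {
    abort("Query and reference embeddings must share dimensions.")
  }
  if (length(labels) != nrow(ref_emb)) {
    abort("`labels` must have one entry per reference cell.")
  }
  if (k > nrow(ref_emb)) abort("`k` must not exceed the reference size.")
  labels <- as.character(labels)
  label_levels <- sort(unique(labels))
  scores <- matrix(0, nrow(query_emb), length(label_levels),
                   dimnames = list(rownames(query_emb), label_levels))
  # squared distances query x ref without forming per-cell loops in R
  q2 <- rowSums(query_emb^2); r2 <- rowSums(ref_emb^2)
  d2 <- outer(q2, r2, "+") - 2 * query_emb %*% t(ref_emb)
  d2[d2 < 0] <- 0
  for (i in seq_len(nrow(query_emb))) {
    nb <- order(d2[i, ])[seq_len(k)]
    w <- if (weighting == "uniform") {
      rep(1 / k, k)
    } else {
      h2 <- d2[i, nb[k]]
      if (h2 == 0) rep(1 / k, k) else {
        wv <- exp(-d2[i, nb] / (2 * h2))
        wv / sum(wv)
      }
    }
    for (j in seq_len(k)) {
      scores[i, labels[nb[j]]] <- scores[i, labels[nb[j]]] + w[j]
    }
    scores[i, ] <- scores[i, ] / sum(scores[i, ])
  }
  structure(scores, class = c("prediction_scores", class(scores)),
            weighting = weighting, k = k)
}

#' Assign each query cell its highest-scoring predicted label
#'
#' The reference label with the highest prediction score becomes the
#' predicted label. Exact ties are broken toward the lexicographically
#' first label and flagged.
#'
#' @param s A `prediction_scores` matrix.
#' @return Tibble with `cell_id`, `predicted`, `score`, `tie`.
#' @export
assign_predicted <- function(s) {
  if (!is.matrix(s)) abort("`s` must be a prediction-score matrix.")
  labels <- colnames(s)[order(colnames(s))]
  s <- s[, labels, drop = FALSE]   # lexicographic tie-break via column order
  idx <- apply(s, 1, which.max)
  best <- s[cbind(seq_len(nrow(s)), idx)]
  tie <- vapply(seq_len(nrow(s)),
                function(i) sum(s[i, ] == best[i]) > 1, logical(1))
  tibble(cell_id = rownames(s) %||% as.character(seq_len(nrow(s))),
         predicted = labels[idx], score = as.numeric(best), tie = tie)
}
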