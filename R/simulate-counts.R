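# Synthetic single-cell count matrices with planted clusters, marker
# enrichment, mitochondrial content and variable library sizes.

#' Default seven-cluster gastruloid marker panel
#'
#' Canonical marker genes for the seven cell types found in
#' BMP4-differentiated gastruloids. Some genes are deliberately shared
#' between clusters (e.g. SOX17 and PRDM1 between Endoderm and the
#' PGC-like cluster, NANOG between epiblast and PGC-like), mirroring
#' real co-expression structure.
#'
#' @return Named list of character vectors.
#' @export
gastruloid_marker_panel <- function() {
  list(
    "EPI-like"   = c("NANOG", "POU5F1", "DPPA4", "GDF3", "NODAL", "TDGF1"),
    "Ectoderm"   = c("SOX2", "NES", "VIM", "DLK1", "GLI3", "SFRP1"),
    "Mesoderm-1" = c("T", "MIXL1", "EOMES", "GSC"),
    "Mesoderm-2" = c("MESP1", "TBX6", "LHX1", "SNAI1", "PDGFRA", "APLNR"),
    "Endoderm"   = c("SOX17", "FOXA2", "GATA6", "PRDM1"),
    "hPGCLC"     = c("NANOS3", "TFAP2C", "SOX17", "PRDM1", "NANOG"),
    "ExE-like"   = c("CDX2", "GATA3", "KRT7", "TFAP2A", "WNT6", "HAND1"))
}

#' Specification of a synthetic count matrix
#'
#' Describes a genes-by-cells count simulation with planted clusters.
#' Counts are drawn from an overdispersed (gamma-Poisson) model: each
#' gene gets a log-normal baseline mean, marker genes are elevated
#' `marker_fold_change`-fold in their cluster, per-cell expected totals
#' are drawn from `library_size_range`, and a per-cell mitochondrial
#' fraction from `mito_fraction_range` is routed to `mito_gene_count`
#' genes named with `mito_prefix`. Defaults emulate the gastruloid
#' experiment: seven clusters totalling 2475 cells in proportions
#' matching the two pooled replicates, with the canonical marker panel.
#'
#' @param n_cells_per_cluster Named integer vector, cells per planted
#'   cluster.
#' @param n_genes Total number of genes, at least the union of marker
#'   lists plus mitochondrial genes.
#' @param markers_per_cluster Named list mapping cluster to marker gene
#'   names; lists may share genes. Entries for clusters absent from
#'   `n_cells_per_cluster` contribute their genes to the gene universe
#'   without elevating them anywhere.
#' @param marker_fold_change Multiplicative elevation of a marker in its
#'   cluster (> 1).
#' @param marker_background `"baseline"` keeps a marker's log-normal
#'   baseline outside its cluster; `"zero"` silences it there.
#' @param mito_gene_count Number of mitochondrial genes.
#' @param mito_fraction_range Length-2 range of per-cell mitochondrial
#'   count fractions.
#' @param library_size_range Length-2 range of per-cell expected totals.
#' @param exact_library_size If `TRUE`, cell totals equal the drawn
#'   library size exactly (gamma-weighted multinomial allocation keeps
#'   the overdispersion); if `FALSE` totals vary around it.
#' @param dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param stage_labels Optional named character vector mapping cluster to
#'   a developmental stage label, for reference datasets.
#' @param n_replicates Cells are split evenly at random across this many
#'   replicates (metadata column `replicate`).
#' @param mito_prefix Gene-name prefix for mitochondrial genes.
#' @param seed Integer seed for cell-level sampling.
#' @param gene_mean_seed Optional integer seed controlling the per-gene
#'   baseline means separately from cell sampling. Two specs sharing a
#'   `gene_mean_seed` (and gene layout) describe draws from the same
#'   gene-level distribution — use this to simulate a query dataset
#'   drawn from a reference's distribution.
#' @return An object of class `count_sim_spec`.
#' @seealso [simulate_counts()]
#' @export
count_sim_spec <- function(n_cells_per_cluster = c(
                             "EPI-like" = 500, "Ectoderm" = 600,
                             "Mesoderm-1" = 400, "Mesoderm-2" = 300,
                             "Endoderm" = 250, "hPGCLC" = 125,
                             "ExE-like" = 300),
                           n_genes = 2000,
                           markers_per_cluster = gastruloid_marker_panel()[
                             names(n_cells_per_cluster)],
                           marker_fold_change = 5,
                           marker_background = c("baseline", "zero"),
                           mito_gene_count = 13,
                           mito_fraction_range = c(0.005, 0.025),
                           library_size_range = c(2000, 10000),
                           exact_library_size = FALSE,
                           dispersion = 2,
                           stage_labels = NULL,
                           n_replicates = 1,
                           mito_prefix = "MT-",
                           seed = 1L,
                           gene_mean_seed = NULL) {
  marker_background <- match.arg(marker_background)
  if (is.null(names(n_cells_per_cluster)) || any(n_cells_per_cluster < 0)) {
    abort("`n_cells_per_cluster` must be a named vector of nonnegative counts.")
  }
  if (!is.list(markers_per_cluster)) {
    abort("`markers_per_cluster` must be a named list of gene vectors.")
  }
  markers_per_cluster <- markers_per_cluster[
    !vapply(markers_per_cluster, is.null, logical(1))]
  # marker lists for clusters not being simulated are allowed: they still
  # define genes (keeping the gene universe comparable across datasets)
  # but elevate nothing
  stop_if_not_scalar_number(marker_fold_change, "marker_fold_change", min = 1 + 1e-9)
  stop_if_not_scalar_number(mito_gene_count, "mito_gene_count", min = 0)
  stop_if_not_scalar_number(dispersion, "dispersion", min = 1e-6)
  for (nm in c("mito_fraction_range", "library_size_range")) {
    r <- get(nm)
    if (length(r) != 2 || r[1] > r[2] || any(r < 0)) {
      abort(sprintf("`%s` must be an ordered nonnegative [low, high] pair.", nm))
    }
  }
  marker_union <- unique(unlist(markers_per_cluster))
  if (n_genes < length(marker_union) + mito_gene_count) {
    abort(sprintf(
      "`n_genes` (%d) is smaller than marker union plus mitochondrial genes (%d).",
      n_genes, length(marker_union) + mito_gene_count))
  }
  if (!is.null(stage_labels) &&
      !all(names(n_cells_per_cluster) %in% names(stage_labels))) {
    abort("`stage_labels` must name every cluster.")
  }

  structure(
    list(n_cells_per_cluster = n_cells_per_cluster, n_genes = as.integer(n_genes),
         markers_per_cluster = markers_per_cluster,
         marker_fold_change = marker_fold_change,
         marker_background = marker_background,
         mito_gene_count = as.integer(mito_gene_count),
         mito_fraction_range = mito_fraction_range,
         library_size_range = library_size_range,
         exact_library_size = isTRUE(exact_library_size),
         dispersion = dispersion, stage_labels = stage_labels,
         n_replicates = as.integer(n_replicates),
         mito_prefix = mito_prefix, seed = as.integer(seed),
         gene_mean_seed = if (!is.null(gene_mean_seed)) as.integer(gene_mean_seed)),
    class = "count_sim_spec")
}

#' Simulate a labeled single-cell count matrix
#'
#' @param spec A [count_sim_spec()].
#' @return A `count_matrix`: list with `counts` (sparse genes x cells
#'   integer matrix), `gene_ids`, `cell_ids`, and `cell_meta` (tibble
#'   with `cell_id`, `cluster`, optional `stage`, `replicate`, and the
#'   derived QC columns `total_counts`, `detected_genes`,
#'   `mito_fraction`).
#' @export
simulate_counts <- function(spec) {
  if (!inherits(spec, "count_sim_spec")) abort("`spec` must be a count_sim_spec.")
  set.seed(spec$seed)

  clusters <- names(spec$n_cells_per_cluster)
  n_cells <- sum(spec$n_cells_per_cluster)
  if (n_cells == 0) abort("Spec yields zero cells.")
  cell_cluster <- rep(clusters, spec$n_cells_per_cluster)

  marker_union <- unique(unlist(spec$markers_per_cluster))
  mito_genes <- if (spec$mito_gene_count > 0) {
    paste0(spec$mito_prefix, seq_len(spec$mito_gene_count))
  } else character(0)
  n_filler <- spec$n_genes - length(marker_union) - length(mito_genes)
  filler <- if (n_filler > 0) sprintf("GENE%05d", seq_len(n_filler)) else character(0)
  gene_ids <- c(marker_union, mito_genes, filler)

  # log-normal baseline means, one per gene; optionally drawn under a
  # dedicated seed so several datasets share one gene-level distribution
  if (!is.null(spec$gene_mean_seed)) set.seed(spec$gene_mean_seed)
  base_mu <- stats::rlnorm(spec$n_genes, meanlog = log(0.5), sdlog = 1.2)
  if (!is.null(spec$gene_mean_seed)) set.seed(spec$seed)
  names(base_mu) <- gene_ids
  is_mito <- gene_ids %in% mito_genes

  # per-cluster relative expression over non-mito genes
  cluster_prob <- matrix(base_mu, nrow = spec$n_genes, ncol = length(clusters),
                         dimnames = list(gene_ids, clusters))
  if (spec$marker_background == "zero" && length(marker_union)) {
    cluster_prob[marker_union, ] <- 0
  }
  for (k in intersect(names(spec$markers_per_cluster), clusters)) {
    mk <- spec$markers_per_cluster[[k]]
    cluster_prob[mk, k] <- base_mu[mk] * spec$marker_fold_change
  }
  # route the drawn mito fraction to mito genes, rest to the others
  cluster_prob[is_mito, ] <- 0
  cluster_prob <- sweep(cluster_prob, 2, colSums(cluster_prob), "/")
  mito_rel <- if (any(is_mito)) base_mu[is_mito] / sum(base_mu[is_mito]) else numeric(0)

  lib_size <- runif(n_cells, spec$library_size_range[1], spec$library_size_range[2])
  if (spec$exact_library_size) lib_size <- round(lib_size)
  mito_frac <- if (any(is_mito)) {
    runif(n_cells, spec$mito_fraction_range[1], spec$mito_fraction_range[2])
  } else rep(0, n_cells)

  counts <- matrix(0L, nrow = spec$n_genes, ncol = n_cells,
                   dimnames = list(gene_ids, NULL))
  size <- spec$dispersion
  for (c_i in seq_len(n_cells)) {
    p <- cluster_prob[, cell_cluster[c_i]] * (1 - mito_frac[c_i])
    if (any(is_mito)) p[is_mito] <- mito_rel * mito_frac[c_i]
    mu <- p * lib_size[c_i]
    if (spec$exact_library_size) {
      # gamma-Poisson: gamma weights then multinomial keeps totals exact
      w <- rgamma(spec$n_genes, shape = size, rate = size) * mu
      if (sum(w) == 0) w <- p
      counts[, c_i] <- stats::rmultinom(1, lib_size[c_i], w)[, 1]
    } else {
      nz <- mu > 0
      counts[nz, c_i] <- rnbinom(sum(nz), mu = mu[nz], size = size)
    }
  }

  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  colnames(counts) <- cell_ids
  replicate <- paste0("rep", sample(rep_len(seq_len(spec$n_replicates), n_cells)))
  meta <- tibble(cell_id = cell_ids, cluster = cell_cluster, replicate = replicate)
  if (!is.null(spec$stage_labels)) {
    meta$stage <- unname(spec$stage_labels[cell_cluster])
  }
  new_count_matrix(Matrix(counts, sparse = TRUE), meta,
                   mito_prefix = spec$mito_prefix)
}

#' Construct a count-matrix container
#'
#' Bundles a genes-by-cells integer count matrix with per-cell metadata
#' and (re)computes the derived QC columns `total_counts`,
#' `detected_genes` and `mito_fraction`.
#'
#' @param counts Genes x cells matrix (dense or sparse) with gene row
#'   names; nonnegative integers.
#' @param cell_meta Optional tibble/data.frame with one row per cell; a
#'   `cell_id` column is added from column names if absent.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @return A `count_matrix` object.
#' @export
new_count_matrix <- function(counts, cell_meta = NULL, mito_prefix = "MT-") {
  if (is.null(rownames(counts))) abort("`counts` needs gene row names.")
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  }
  if (any(counts < 0)) abort("`counts` must be nonnegative.")
  counts <- Matrix(counts, sparse = TRUE)
  if (is.null(cell_meta)) {
    cell_meta <- tibble(cell_id = colnames(counts))
  } else {
    cell_meta <- as_tibble(cell_meta)
    if (!"cell_id" %in% names(cell_meta)) cell_meta$cell_id <- colnames(counts)
    if (nrow(cell_meta) != ncol(counts) ||
        !identical(cell_meta$cell_id, colnames(counts))) {
      abort("`cell_meta` rows must match count matrix columns (by cell_id).")
    }
  }
  totals <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  cell_meta$total_counts <- as.numeric(totals)
  cell_meta$detected_genes <- as.integer(Matrix::colSums(counts > 0))
  cell_meta$mito_fraction <- if (any(mito)) {
    as.numeric(Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1))
  } else 0
  structure(
    list(counts = counts, gene_ids = rownames(counts),
         cell_ids = colnames(counts), cell_meta = cell_meta,
         mito_prefix = mito_prefix),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells; metadata: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(names(x$cell_meta), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
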