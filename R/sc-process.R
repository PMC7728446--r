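# Normalization, HVG selection, scaling with covariate removal, PCA.

#' Log-normalize a count matrix
#'
#' Scales each cell's counts to `scale_factor` total and applies
#' `log(1 + x)` — the counts-per-10,000 convention of standard
#' single-cell toolkits. Doubling every count of a cell leaves its
#' normalized profile unchanged.
#'
#' @param m A `count_matrix`.
#' @param scale_factor Per-cell target total before the log transform.
#' @return A `processed_matrix`: list with `lognorm` (genes x cells),
#'   `cell_meta`, and slots `hvg`, `scaled`, `pca` filled by
#'   [select_hvg()], [scale_regress()] and [run_pca()].
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  if (!inherits(m, "count_matrix")) abort("`m` must be a count_matrix.")
  stop_if_not_scalar_number(scale_factor, "scale_factor", min = 1e-9)
  totals <- Matrix::colSums(m$counts)
  if (any(totals == 0)) {
    abort("Cell(s) with zero total counts present; they should have failed QC.")
  }
  lognorm <- m$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(m$counts)
  structure(
    list(lognorm = lognorm, cell_meta = m$cell_meta,
         scale_factor = scale_factor, hvg = NULL, scaled = NULL, pca = NULL),
    class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("<processed_matrix> %d genes x %d cells; hvg: %s; scaled: %s; pca: %s\n",
              nrow(x$lognorm), ncol(x$lognorm),
              if (is.null(x$hvg)) "-" else length(x$hvg),
              if (is.null(x$scaled)) "-" else paste(dim(x$scaled), collapse = "x"),
              if (is.null(x$pca)) "-" else ncol(x$pca)))
  invisible(x)
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion standardized within mean-expression bins:
#' per-gene mean and variance-to-mean dispersion are computed on the
#' de-logged normalized data, genes are cut into `n_mean_bins` bins of
#' comparable mean expression, and dispersions are z-scored within each
#' bin. The top `n` genes by standardized dispersion are returned.
#' Constant genes have no dispersion and are never selected while any
#' varying gene remains.
#'
#' @param p A `processed_matrix`.
#' @param n Number of genes to select (default 2000).
#' @param n_mean_bins Number of mean-expression bins.
#' @return Character vector of gene names, ordered by decreasing
#'   standardized dispersion.
#' @export
select_hvg <- function(p, n = 2000, n_mean_bins = 20) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  n <- min(n, nrow(p$lognorm))
  expd <- expm1(as.matrix(p$lognorm))
  mu <- rowMeans(expd)
  v <- apply(expd, 1, stats::var)
  disp <- ifelse(mu > 0 & v > 0, v / mu, NA_real_)

  bins <- cut(mu, breaks = unique(quantile(mu, probs = seq(0, 1, length.out = n_mean_bins + 1))),
              include.lowest = TRUE)
  z <- rep(-Inf, length(mu))   # constant / silent genes rank last
  for (b in levels(bins)) {
    i <- which(bins == b & !is.na(disp))
    if (!length(i)) next
    m_b <- mean(disp[i]); s_b <- sd(disp[i])
    z[i] <- if (is.na(s_b) || s_b == 0) 0 else (disp[i] - m_b) / s_b
  }
  ord <- order(z, decreasing = TRUE)
  rownames(p$lognorm)[head(ord, n)]
}

#' Scale expression and regress out unwanted covariates
#'
#' For each gene (restricted to `genes`, by default a fresh HVG
#' selection), fits a linear model of log-normalized expression on the
#' supplied per-cell covariates, keeps the residuals, then standardizes
#' each gene to mean 0 / sd 1 and clips values at `clip` (default
#' +/- 10) to stop outliers dominating downstream embeddings. Typical
#' covariates are the mitochondrial fraction, total counts, and
#' cell-cycle scores from [module_score()].
#'
#' @param p A `processed_matrix`.
#' @param covariates `NULL` for pure standardization; otherwise a
#'   data.frame/matrix of per-cell covariates, or a character vector of
#'   `cell_meta` column names.
#' @param genes Genes to scale; defaults to [select_hvg()] with
#'   `n_hvg`.
#' @param n_hvg HVG count used when `genes` is `NULL`.
#' @param clip Symmetric clipping bound on the scaled values.
#' @return `p` with `scaled` (genes x cells dense matrix) and `hvg`
#'   filled in.
#' @export
scale_regress <- function(p, covariates = NULL, genes = NULL,
                          n_hvg = 2000, clip = 10) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  stop_if_not_scalar_number(clip, "clip", min = 1e-9)
  if (is.null(genes)) genes <- select_hvg(p, n = n_hvg)
  if (!all(genes %in% rownames(p$lognorm))) {
    abort("Some `genes` are absent from the matrix.")
  }
  y <- as.matrix(p$lognorm[genes, , drop = FALSE])

  if (!is.null(covariates)) {
    if (is.character(covariates)) {
      missing_cov <- setdiff(covariates, names(p$cell_meta))
      if (length(missing_cov)) {
        abort(sprintf("Covariate column(s) not in cell_meta: %s.",
                      paste(missing_cov, collapse = ", ")))
      }
      covariates <- p$cell_meta[covariates]
    }
    x <- as.matrix(as.data.frame(covariates))
    if (nrow(x) != ncol(y)) abort("Covariates must have one row per cell.")
    keep <- apply(x, 2, function(col) sd(col) > 0)
    if (!all(keep)) {
      warn(sprintf("Dropping constant covariate(s): %s.",
                   paste(colnames(x)[!keep], collapse = ", ")))
      x <- x[, keep, drop = FALSE]
    }
    if (ncol(x) > 0) {
      qr_x <- qr(cbind(`(Intercept)` = 1, x))
      y <- t(qr.resid(qr_x, t(y)))
    }
  }

  mu <- rowMeans(y)
  s <- apply(y, 1, sd)
  # genes with essentially no residual variance stay at zero rather than
  # having numerical noise inflated to unit variance
  s[s < 1e-8] <- Inf
  y <- (y - mu) / s
  y[y > clip] <- clip
  y[y < -clip] <- -clip

  p$scaled <- y
  p$hvg <- genes
  p
}

#' Principal component analysis of the scaled matrix
#'
#' Cells x genes PCA on the scaled matrix, returning variance-ordered
#' components. Component signs are fixed (largest-magnitude loading made
#' positive) so results are deterministic.
#'
#' @param p A `processed_matrix` with `scaled` filled in.
#' @param n_pc Number of components (default 15).
#' @return `p` with `pca` (cells x n_pc score matrix, attribute `sdev`)
#'   and `pca_rotation` filled in.
#' @export
run_pca <- function(p, n_pc = 15) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  if (is.null(p$scaled)) abort("Run scale_regress() before run_pca().")
  n_pc <- as.integer(n_pc)
  if (n_pc > min(dim(p$scaled))) {
    abort(sprintf("`n_pc` (%d) exceeds min(genes, cells) = %d.",
                  n_pc, min(dim(p$scaled))))
  }
  pc <- prcomp(t(p$scaled), center = FALSE, scale. = FALSE, rank. = n_pc)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  rotation <- sweep(pc$rotation, 2, flip, "*")
  rownames(scores) <- colnames(p$scaled)
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pc)]
  p$pca <- scores
  p$pca_rotation <- rotation
  p
}
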