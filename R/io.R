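# Readers and writers for the standard on-disk formats: multi-page
# TIFF / per-channel PNG images, centroid CSV, 10x-style MTX triplets
# and dense TSV count matrices.

#' Write a colony's channels as a multi-page TIFF
#'
#' One page per channel, float intensities rescaled to [0, 1] per file
#' (the common rescale factor is stored nowhere, so use
#' [write_centroids_csv()] for quantitative ground truth). Channel
#' names go into a sidecar `<path>.channels.txt`.
#'
#' @param image Named list of channel matrices or a `synthetic_colony`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_colony_tiff <- function(image, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to write TIFF files.")
  }
  ch <- get_channels(image)
  top <- max(1e-12, max(vapply(ch, max, numeric(1))))
  tiff::writeTIFF(lapply(ch, function(m) m / top), path,
                  bits.per.sample = 32L)
  writeLines(names(ch), paste0(path, ".channels.txt"))
  invisible(path)
}

#' Read a multi-page TIFF written by [write_colony_tiff()]
#'
#' @param path TIFF path; channel names are read from the sidecar file
#'   when present, else pages are named `ch1`, `ch2`, ...
#' @return Named list of intensity matrices.
#' @export
read_colony_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("Package 'tiff' is required to read TIFF files.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".channels.txt")
  nms <- if (file.exists(sidecar)) readLines(sidecar) else
    paste0("ch", seq_along(pages))
  setNames(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.numeric(p), nrow(p), ncol(p))
  }), nms)
}

#' Write centroid ground truth as CSV
#'
#' One row per cell: `x_px`, `y_px`, `markers` (semicolon-joined marker
#' labels of that cell).
#'
#' @param centroids Long centroid tibble (`cell_id`, `x_px`, `y_px`,
#'   `marker`) or a `synthetic_colony`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_centroids_csv <- function(centroids, path) {
  if (inherits(centroids, "synthetic_colony")) centroids <- centroids$centroids
  wide <- centroids |>
    dplyr::group_by(.data$cell_id, .data$x_px, .data$y_px) |>
    dplyr::summarise(markers = paste(sort(.data$marker), collapse = ";"),
                     .groups = "drop") |>
    dplyr::select("x_px", "y_px", "markers")
  readr::write_csv(wide, path)
  invisible(path)
}

#' Read a centroid CSV into the long per-marker format
#'
#' @param path CSV with `x_px`, `y_px`, `markers` (semicolon-joined).
#' @return Tibble with `cell_id`, `x_px`, `y_px`, `marker` (one row per
#'   cell-marker pair).
#' @export
read_centroids_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  wide$cell_id <- seq_len(nrow(wide))
  tidyr::separate_rows(wide, "markers", sep = ";") |>
    dplyr::rename(marker = "markers") |>
    dplyr::select("cell_id", "x_px", "y_px", "marker")
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and (when
#' metadata is present) `cell_meta.tsv` into `dir`.
#'
#' @param m A `count_matrix`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(m, dir) {
  if (!inherits(m, "count_matrix")) abort("`m` must be a count_matrix.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  if (!is.null(m$cell_meta)) {
    readr::write_tsv(m$cell_meta, file.path(dir, "cell_meta.tsv"))
  }
  invisible(dir)
}

#' Read a 10x-style MTX triplet into a count matrix
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, optionally `cell_meta.tsv`.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @return A `count_matrix`.
#' @export
read_counts_mtx <- function(dir, mito_prefix = "MT-") {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "features.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- if (file.exists(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  } else NULL
  new_count_matrix(counts, meta, mito_prefix = mito_prefix)
}

#' Write a count matrix as dense TSV
#'
#' Genes in rows (first column `gene`), cells in columns.
#'
#' @param m A `count_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  if (!inherits(m, "count_matrix")) abort("`m` must be a count_matrix.")
  df <- as.data.frame(as.matrix(m$counts))
  df <- cbind(gene = m$gene_ids, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a dense TSV count matrix
#'
#' @param path TSV with a `gene` column followed by one column per cell.
#' @param mito_prefix Mitochondrial gene-name prefix.
#' @return A `count_matrix`.
#' @export
read_counts_tsv <- function(path, mito_prefix = "MT-") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  genes <- df[[1]]
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- genes
  new_count_matrix(counts, mito_prefix = mito_prefix)
}
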