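# Cell-level quality control with exclusive thresholds.

#' Quality-control thresholds for cell filtering
#'
#' A cell is retained when `min_genes < detected_genes < max_genes` and
#' `mito_fraction < max_mito_fraction`; all bounds are exclusive, so a
#' cell with exactly `min_genes` detected genes is removed.
#'
#' @param min_genes,max_genes Exclusive bounds on detected genes.
#' @param max_mito_fraction Exclusive upper bound on the mitochondrial
#'   count fraction, in (0, 1].
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 7500,
                          max_mito_fraction = 0.03) {
  stop_if_not_scalar_number(min_genes, "min_genes", min = 0)
  stop_if_not_scalar_number(max_genes, "max_genes", min = 0, allow_inf = TRUE)
  stop_if_not_scalar_number(max_mito_fraction, "max_mito_fraction",
                            min = 1e-12, max = 1)
  if (min_genes >= max_genes) abort("`min_genes` must be below `max_genes`.")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "qc_thresholds")
}

#' Replicate-specific gastruloid QC thresholds
#'
#' The thresholds used for the two gastruloid scRNA-seq replicates:
#' replicate 1 removes cells with <= 200 or >= 7500 detected genes or
#' >= 3% mitochondrial counts; replicate 2 uses 6000 genes and 2.5%.
#'
#' @return Named list of [qc_thresholds()] keyed by replicate
#'   (`rep1`, `rep2`).
#' @export
gastruloid_qc_thresholds <- function() {
  list(rep1 = qc_thresholds(200, 7500, 0.03),
       rep2 = qc_thresholds(200, 6000, 0.025))
}

#' Filter cells by quality control
#'
#' Applies exclusive gene-count and mitochondrial-fraction thresholds to
#' a count matrix. Thresholds may be a single [qc_thresholds()] applied
#' to every cell, or a named list keyed by the `replicate` metadata
#' column for replicate-specific cutoffs. QC columns are recomputed from
#' the counts before filtering, and a per-replicate pass/fail report is
#' attached to the result.
#'
#' @param m A `count_matrix`.
#' @param thresholds A [qc_thresholds()] or a named list of them keyed
#'   by replicate.
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes;
#'   defaults to the prefix stored in `m`.
#' @return The filtered `count_matrix`, with attribute `qc_report` (a
#'   tibble of per-replicate totals) also retrievable via
#'   [qc_report()].
#' @export
qc_filter <- function(m, thresholds = qc_thresholds(),
                      mito_prefix = NULL) {
  if (!inherits(m, "count_matrix")) abort("`m` must be a count_matrix.")
  mito_prefix <- mito_prefix %||% m$mito_prefix %||% "MT-"
  # recompute derived QC columns so stale metadata cannot leak through
  m <- new_count_matrix(m$counts, m$cell_meta, mito_prefix = mito_prefix)
  meta <- m$cell_meta

  per_replicate <- is.list(thresholds) && !inherits(thresholds, "qc_thresholds")
  if (per_replicate) {
    if (!"replicate" %in% names(meta)) {
      abort("Replicate-specific thresholds need a `replicate` metadata column.")
    }
    missing_rep <- setdiff(unique(meta$replicate), names(thresholds))
    if (length(missing_rep)) {
      abort(sprintf("No thresholds for replicate(s): %s.",
                    paste(missing_rep, collapse = ", ")))
    }
    if (!all(vapply(thresholds, inherits, logical(1), "qc_thresholds"))) {
      abort("Each element of `thresholds` must be a qc_thresholds object.")
    }
  } else if (!inherits(thresholds, "qc_thresholds")) {
    abort("`thresholds` must be a qc_thresholds object or a named list of them.")
  }

  pass_one <- function(t, genes, mito) {
    genes > t$min_genes & genes < t$max_genes & mito < t$max_mito_fraction
  }
  if (per_replicate) {
    pass <- logical(nrow(meta))
    for (r in unique(meta$replicate)) {
      i <- meta$replicate == r
      pass[i] <- pass_one(thresholds[[r]], meta$detected_genes[i],
                          meta$mito_fraction[i])
    }
  } else {
    pass <- pass_one(thresholds, meta$detected_genes, meta$mito_fraction)
  }
  if (!any(pass)) abort("No cells pass quality control.")

  rep_col <- if ("replicate" %in% names(meta)) meta$replicate else
    rep("all", nrow(meta))
  report <- as_tibble(as.data.frame(table(replicate = rep_col, pass = pass)))
  report <- tidyr::pivot_wider(report, names_from = "pass",
                               values_from = "Freq",
                               names_prefix = "pass_")
  names(report)[names(report) == "pass_TRUE"] <- "n_pass"
  names(report)[names(report) == "pass_FALSE"] <- "n_fail"
  if (!"n_fail" %in% names(report)) report$n_fail <- 0L
  if (!"n_pass" %in% names(report)) report$n_pass <- 0L
  report$n_total <- report$n_pass + report$n_fail

  out <- new_count_matrix(m$counts[, pass, drop = FALSE],
                          meta[pass, , drop = FALSE],
                          mito_prefix = mito_prefix)
  attr(out, "qc_report") <- report[, c("replicate", "n_total", "n_pass", "n_fail")]
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param m A filtered `count_matrix`.
#' @return Tibble with per-replicate `n_total`, `n_pass`, `n_fail`.
#' @export
qc_report <- function(m) {
  rep <- attr(m, "qc_report")
  if (is.null(rep)) abort("`m` carries no QC report; run qc_filter() first.")
  rep
}
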