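# Gene-set module scores with expression-bin-matched random controls.

#' Read gene sets from JSON
#'
#' Gene sets are stored as a JSON object mapping set name to a gene
#' array. The package ships `gene_sets.json` with the PGC signature and
#' editable S/G2M cell-cycle lists.
#'
#' @param path JSON file; default the shipped file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path = system.file("extdata", "gene_sets.json",
                                              package = "gastrukit")) {
  sets <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(sets, as.character)
}

#' The primordial-germ-cell signature gene set
#'
#' The five-gene PGC signature (NANOS3, SOX17, TFAP2C, PRDM1, NANOG)
#' used to score PGC-like identity.
#'
#' @return Character vector of gene names.
#' @export
pgc_gene_set <- function() {
  read_gene_sets()[["pgc_signature"]]
}

#' Gene-set module score
#'
#' Scores every cell for a gene set as the average log-normalized
#' expression of the set genes minus that of randomly chosen control
#' genes matched on expression level: all genes are binned into
#' `n_bins` equal-count bins of mean expression, and each set gene
#' contributes `n_ctrl` controls drawn from its own bin. Adding a
#' constant to the set genes' expression raises every cell's score by
#' that constant; a random gene set scores near 0 on average.
#'
#' @param p A `processed_matrix`.
#' @param genes Character vector of set genes; members absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Number of expression bins (default 24).
#' @param n_ctrl Controls drawn per set gene (default 100, capped at the
#'   bin size).
#' @param seed Integer seed for the control draw.
#' @param control_genes Optional explicit control gene vector overriding
#'   the random draw (e.g. for calibration checks).
#' @return Named numeric vector, one score per cell, with attribute
#'   `control_spec`.
#' @export
module_score <- function(p, genes, n_bins = 24, n_ctrl = 100, seed = 1L,
                         control_genes = NULL) {
  if (!inherits(p, "processed_matrix")) abort("`p` must be a processed_matrix.")
  all_genes <- rownames(p$lognorm)
  present <- intersect(genes, all_genes)
  if (length(present) == 0) {
    abort("No gene-set member is present in the matrix.")
  }
  if (length(present) < length(genes)) {
    warn(sprintf("Dropping %d gene(s) absent from the matrix: %s.",
                 length(genes) - length(present),
                 paste(setdiff(genes, present), collapse = ", ")))
  }
  y <- as.matrix(p$lognorm)

  if (is.null(control_genes)) {
    mu <- rowMeans(y)
    # equal-count bins on mean expression
    br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
    bins <- cut(mu, breaks = br, include.lowest = TRUE)
    names(bins) <- all_genes
    set.seed(as.integer(seed))
    ctrl <- character(0)
    for (g in present) {
      pool <- all_genes[bins == bins[g]]
      ctrl <- c(ctrl, sample(pool, size = min(n_ctrl, length(pool))))
    }
    control_genes <- unique(ctrl)
  } else {
    control_genes <- intersect(control_genes, all_genes)
    if (length(control_genes) == 0) abort("No control gene present in the matrix.")
  }

  score <- colMeans(y[present, , drop = FALSE]) -
    colMeans(y[control_genes, , drop = FALSE])
  attr(score, "control_spec") <- list(n_bins = n_bins, n_ctrl = n_ctrl,
                                      seed = as.integer(seed),
                                      n_controls_used = length(control_genes))
  score
}
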