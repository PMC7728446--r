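# Probabilistic breadth-first-search pseudotime on the kNN graph.

#' Pseudotime by probabilistic breadth-first search
#'
#' Orders cells along a differentiation progression by repeated
#' stochastic floods of the k-nearest-neighbor graph from designated
#' root cells. In each simulation a random subset of the roots seeds
#' the search; at every step a random fraction of the current frontier's
#' unvisited neighbors is admitted, and each cell records the step at
#' which it was first visited, normalized by that simulation's total
#' depth. A cell's pseudotime is the mean normalized visit step across
#' simulations, rescaled to [0, 1] with roots fixed at 0. Cells
#' unreachable from the roots get `NA` and are reported.
#'
#' @param d A `diffusion_result` (its kNN-union graph is used) or a
#'   square logical/0-1 adjacency matrix.
#' @param roots Character vector of root cell ids (or integer indices).
#' @param n_sims Number of flood simulations (default 100).
#' @param cells_per_step_fraction Fraction of the eligible frontier
#'   admitted per step (default 0.8).
#' @param root_subsample Fraction of roots seeding each simulation
#'   (default 0.8).
#' @param seed Integer seed; fixed seed gives bit-identical pseudotime.
#' @return Tibble with `cell_id`, `pseudotime`, `n_visits`; attributes
#'   `root_cells`, `n_sims`, `seed`.
#' @export
pseudotime_pbfs <- function(d, roots, n_sims = 100,
                            cells_per_step_fraction = 0.8,
                            root_subsample = 0.8, seed = 1L) {
  adj <- if (inherits(d, "diffusion_result")) {
    a <- d$knn_adjacency
    dimnames(a) <- dimnames(d$transition)
    a
  } else {
    as.matrix(d) != 0
  }
  n <- nrow(adj)
  ids <- rownames(adj) %||% as.character(seq_len(n))
  if (is.character(roots)) {
    root_idx <- match(roots, ids)
    if (anyNA(root_idx)) abort("Some `roots` are not in the graph.")
  } else {
    root_idx <- as.integer(roots)
    if (any(root_idx < 1 | root_idx > n)) abort("Root indices out of range.")
  }
  if (length(root_idx) == 0) abort("`roots` must be nonempty.")
  stop_if_not_scalar_number(cells_per_step_fraction, "cells_per_step_fraction",
                            min = 1e-9, max = 1)
  stop_if_not_scalar_number(root_subsample, "root_subsample",
                            min = 1e-9, max = 1)
  neighbors <- apply(adj, 1, which, simplify = FALSE)

  set.seed(as.integer(seed))
  sum_pt <- numeric(n)
  n_visits <- integer(n)
  for (s in seq_len(n_sims)) {
    n_seed <- max(1L, ceiling(root_subsample * length(root_idx)))
    seeds <- if (length(root_idx) == 1) root_idx else
      sample(root_idx, n_seed)
    step <- rep(NA_integer_, n)
    step[seeds] <- 0L
    frontier <- seeds
    t_step <- 0L
    while (length(frontier) > 0) {
      cand <- unique(unlist(neighbors[frontier], use.names = FALSE))
      cand <- cand[is.na(step[cand])]
      if (length(cand) == 0) break
      n_take <- max(1L, ceiling(cells_per_step_fraction * length(cand)))
      take <- if (length(cand) == 1) cand else sample(cand, n_take)
      t_step <- t_step + 1L
      step[take] <- t_step
      frontier <- take
    }
    step[root_idx] <- 0L   # roots define the origin
    if (t_step > 0) {
      visited <- !is.na(step)
      sum_pt[visited] <- sum_pt[visited] + step[visited] / t_step
      n_visits[visited] <- n_visits[visited] + 1L
    }
  }

  pt <- ifelse(n_visits > 0, sum_pt / n_visits, NA_real_)
  if (anyNA(pt)) {
    warn(sprintf("%d cell(s) were never reached from the roots; pseudotime NA.",
                 sum(is.na(pt))))
  }
  finite <- is.finite(pt)
  rng <- range(pt[finite])
  pt[finite] <- if (diff(rng) > 0) (pt[finite] - rng[1]) / diff(rng) else 0

  out <- tibble(cell_id = ids, pseudotime = pt, n_visits = n_visits)
  attr(out, "root_cells") <- ids[root_idx]
  attr(out, "n_sims") <- as.integer(n_sims)
  attr(out, "seed") <- as.integer(seed)
  out
}
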