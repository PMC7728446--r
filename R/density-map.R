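# Density-map construction, cell counting and the cosine spatial-overlap
# statistic.

#' Build a density map from annotated centroids
#'
#' Converts a centroid annotation into a density map: a nonnegative grid
#' whose value at a pixel is the expected number of cells there. Each
#' centroid of the requested marker deposits one unit of mass as an
#' isotropic bell-shaped (Gaussian) kernel, truncated at the grid
#' boundary and renormalized so every centroid contributes exactly unit
#' mass. The total mass of the map is therefore the cell count.
#'
#' @param centroids Tibble/data.frame with `x_px`, `y_px` and (if
#'   `marker` is given) a `marker` column, in 0-based pixel coordinates;
#'   or a `synthetic_colony`, whose centroid table is used.
#' @param marker Optional marker name to select; `NULL` uses every
#'   distinct centroid (rows deduplicated by `cell_id` when present).
#' @param shape Grid dimensions `c(nrow, ncol)`.
#' @param kernel_sigma_px Kernel width (standard deviation, pixels).
#' @return A `density_map`: a matrix with attributes `source`
#'   (`"annotation"`), `n_centroids` and `sigma`.
#' @export
density_from_centroids <- function(centroids, marker = NULL, shape,
                                   kernel_sigma_px = 8) {
  if (inherits(centroids, "synthetic_colony")) {
    if (missing(shape)) shape <- dim(centroids$channels[[1]])
    centroids <- centroids$centroids
  }
  stop_if_not_scalar_number(kernel_sigma_px, "kernel_sigma_px", min = 1e-9)
  if (length(shape) != 2 || any(shape < 1)) abort("`shape` must be c(nrow, ncol).")
  df <- as.data.frame(centroids)
  if (!all(c("x_px", "y_px") %in% names(df))) {
    abort("`centroids` needs `x_px` and `y_px` columns.")
  }
  if (!is.null(marker)) {
    if (!"marker" %in% names(df)) abort("`centroids` has no `marker` column.")
    df <- df[df$marker == marker, , drop = FALSE]
  } else if ("cell_id" %in% names(df)) {
    df <- df[!duplicated(df$cell_id), , drop = FALSE]
  }
  if (nrow(df) > 0 &&
      (any(df$x_px < 0) || any(df$x_px > shape[2] - 1) ||
       any(df$y_px < 0) || any(df$y_px > shape[1] - 1))) {
    abort("Centroid(s) fall outside the grid.")
  }

  values <- matrix(0, shape[1], shape[2])
  half <- ceiling(4 * kernel_sigma_px)
  for (i in seq_len(nrow(df))) {
    cx <- df$x_px[i]; cy <- df$y_px[i]
    xs <- max(0, round(cx) - half):min(shape[2] - 1, round(cx) + half)
    ys <- max(0, round(cy) - half):min(shape[1] - 1, round(cy) + half)
    kern <- outer(exp(-((ys - cy)^2) / (2 * kernel_sigma_px^2)),
                  exp(-((xs - cx)^2) / (2 * kernel_sigma_px^2)))
    values[ys + 1, xs + 1] <- values[ys + 1, xs + 1] + kern / sum(kern)
  }
  new_density_map(values, source = "annotation", n_centroids = nrow(df),
                  sigma = kernel_sigma_px)
}

new_density_map <- function(values, source, n_centroids = NA_integer_,
                            sigma = NA_real_) {
  structure(values, class = c("density_map", class(values)),
            source = source, n_centroids = n_centroids, sigma = sigma)
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %dx%d, source = %s, total mass = %.4f\n",
              nrow(x), ncol(x), attr(x, "source"), sum(x)))
  invisible(x)
}

#' Expected cell count of a density map
#'
#' The total number of cells represented by a density map is the sum of
#' all its densities, \eqn{C = \sum_i \sum_j Y_{ij}}. For
#' annotation-sourced maps this equals the number of contributing
#' centroids.
#'
#' @param map A `density_map` or plain nonnegative matrix.
#' @return Scalar expected cell count.
#' @export
cell_count <- function(map) {
  if (!is.matrix(map)) abort("`map` must be a matrix.")
  if (any(map < 0)) abort("Density maps must be nonnegative.")
  sum(map)
}

#' Cosine spatial overlap of two density maps
#'
#' Measures how much the spatial distributions of two cell populations
#' overlap, as the cosine similarity of their density maps:
#' \deqn{CosSim = \frac{\sum_{ij} Y'_{ij} Y_{ij}}
#'   {\sqrt{\sum_{ij} Y'^2_{ij}} \sqrt{\sum_{ij} Y^2_{ij}}}.}
#' Values range from 0 (disjoint populations) to 1 (identical spatial
#' distribution), and are invariant to scaling either map.
#'
#' @param a,b Density maps (or plain nonnegative matrices) of identical
#'   shape, each with at least one nonzero entry.
#' @return Scalar in `[0, 1]`.
#' @export
cosine_overlap <- function(a, b) {
  if (!is.matrix(a) || !is.matrix(b) || !identical(dim(a), dim(b))) {
    abort("`a` and `b` must be matrices of identical shape.")
  }
  if (any(a < 0) || any(b < 0)) abort("Density maps must be nonnegative.")
  na2 <- sum(a^2); nb2 <- sum(b^2)
  if (na2 == 0 || nb2 == 0) {
    abort("Cosine overlap is undefined for an all-zero map.")
  }
  sum(a * b) / (sqrt(na2) * sqrt(nb2))
}

#' Detect cell centroids by local-maximum blob detection
#'
#' A simple intensity-based stand-in for learned density-map estimators:
#' candidate pixels are local maxima (3x3 neighborhood) above
#' `min_intensity`; candidates are then accepted greedily in order of
#' decreasing intensity, suppressing any candidate closer than
#' `min_separation_px` to an accepted one.
#'
#' @param image Named list of channel matrices or a `synthetic_colony`.
#' @param channel Channel to detect in.
#' @param min_intensity Absolute intensity threshold (>= 0).
#' @param min_separation_px Minimum distance between detected centroids.
#' @return Tibble with `x_px`, `y_px` (0-based), `marker`, `intensity`;
#'   empty when nothing exceeds the threshold.
#' @export
detect_centroids <- function(image, channel, min_intensity = 0.5,
                             min_separation_px = 4) {
  m <- get_channel(image, channel)
  stop_if_not_scalar_number(min_intensity, "min_intensity", min = 0)
  stop_if_not_scalar_number(min_separation_px, "min_separation_px", min = 0)

  pad <- matrix(-Inf, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  is_max <- m >= min_intensity
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    shifted <- pad[(2 + dy):(nrow(m) + 1 + dy), (2 + dx):(ncol(m) + 1 + dx)]
    is_max <- is_max & (m >= shifted)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(x_px = numeric(0), y_px = numeric(0),
                  marker = character(0), intensity = numeric(0)))
  }
  cand <- data.frame(x = idx[, "col"] - 1, y = idx[, "row"] - 1,
                     val = m[idx])
  cand <- cand[order(-cand$val), , drop = FALSE]

  keep_x <- numeric(0); keep_y <- numeric(0); keep_v <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep_x) == 0 ||
        all((keep_x - cand$x[i])^2 + (keep_y - cand$y[i])^2 >=
            min_separation_px^2)) {
      keep_x <- c(keep_x, cand$x[i])
      keep_y <- c(keep_y, cand$y[i])
      keep_v <- c(keep_v, cand$val[i])
    }
  }
  tibble(x_px = keep_x, y_px = keep_y, marker = channel, intensity = keep_v)
}
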