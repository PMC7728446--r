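# Synthetic colony rendering: centroid placement in concentric rings and
# Gaussian-bump channel images with known ground truth.

#' Simulate a multi-channel colony image with known centroids
#'
#' Places cells in the concentric marker rings described by a
#' [colony_spec()], then renders one intensity channel per marker plus a
#' DAPI channel with a bump at every nucleus. The returned centroid
#' table is the exhaustive ground truth used by the density-map and
#' detection operations; a cell co-expressing two markers is a single
#' centroid listed under both markers.
#'
#' @param spec A [colony_spec()].
#' @return A `synthetic_colony`: list with `channels` (named list of
#'   matrices, rows = y, columns = x, 0-based pixel-center coordinates),
#'   `centroids` (tibble with `cell_id`, `x_px`, `y_px`, `marker`; one
#'   row per cell-marker pair), and `spec`.
#' @export
simulate_colony <- function(spec) {
  if (!inherits(spec, "colony_spec")) abort("`spec` must be a colony_spec.")
  n_px <- ceiling(spec$diameter_um / spec$pixel_size_um)
  # cap at the grid half-extent so every centroid lies on the pixel grid
  radius_px <- min(spec$diameter_um / (2 * spec$pixel_size_um), (n_px - 1) / 2)
  center <- (n_px - 1) / 2  # both x and y

  set.seed(spec$seed)
  cells <- place_cells(spec, center, radius_px)

  channels <- list()
  markers <- names(spec$ring_layout)
  # one distinct nucleus per cell_id
  nuclei <- cells[!duplicated(cells$cell_id), , drop = FALSE]
  channels[["DAPI"]] <- render_spots(
    nuclei$x_px, nuclei$y_px, n_px, spec$spot_sigma_px, spec$background_noise_sd)
  for (m in markers) {
    sub <- cells[cells$marker == m, , drop = FALSE]
    channels[[m]] <- render_spots(
      sub$x_px, sub$y_px, n_px, spec$spot_sigma_px, spec$background_noise_sd)
  }

  structure(
    list(channels = channels,
         centroids = as_tibble(cells),
         spec = spec),
    class = "synthetic_colony")
}

# sample centroids ring by ring; coexpressing cells drawn once and listed
# under both markers of the rule's pair
place_cells <- function(spec, center, radius_px) {
  markers <- names(spec$ring_layout)
  n_solo <- spec$cells_per_marker[markers]
  n_solo[is.na(n_solo)] <- 0

  co <- list()
  if (length(spec$coexpression_rules)) {
    for (rule in names(spec$coexpression_rules)) {
      pair <- strsplit(rule, ":", fixed = TRUE)[[1]]
      cap <- min(n_solo[pair[1]], n_solo[pair[2]])
      n_co <- rbinom(1L, cap, spec$coexpression_rules[[rule]])
      if (n_co > 0) {
        co[[rule]] <- list(pair = pair, n = n_co)
        n_solo[pair] <- n_solo[pair] - n_co
      }
    }
  }

  rows <- list()
  next_id <- 1L
  emit <- function(n, ring_marker, carried_markers) {
    if (n == 0) return(NULL)
    frac <- spec$ring_layout[[ring_marker]]
    pos <- sample_annulus(n, center, radius_px, frac[1], frac[2],
                          spec$radial_distribution)
    ids <- seq.int(next_id, length.out = n)
    next_id <<- next_id + n
    do.call(rbind, lapply(carried_markers, function(m) {
      data.frame(cell_id = ids, x_px = pos$x, y_px = pos$y, marker = m,
                 stringsAsFactors = FALSE)
    }))
  }
  for (m in markers) rows[[m]] <- emit(n_solo[[m]], m, m)
  for (rule in names(co)) {
    pair <- co[[rule]]$pair
    rows[[rule]] <- emit(co[[rule]]$n, pair[1], pair)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), x_px = numeric(0),
                      y_px = numeric(0), marker = character(0))
  }
  rownames(out) <- NULL
  out
}

# uniform placement in an annulus between fractions [f_in, f_out] of R
sample_annulus <- function(n, center, radius_px, f_in, f_out, distribution) {
  u <- runif(n)
  r <- if (distribution == "area-uniform") {
    radius_px * sqrt(u * (f_out^2 - f_in^2) + f_in^2)
  } else {
    radius_px * (f_in + u * (f_out - f_in))
  }
  theta <- runif(n, 0, 2 * pi)
  list(x = center + r * cos(theta), y = center + r * sin(theta))
}

# additive isotropic Gaussian bumps (peak amplitude 1) plus clipped noise
render_spots <- function(x, y, n_px, sigma, noise_sd) {
  img <- matrix(0, n_px, n_px)
  if (noise_sd > 0) {
    img <- img + pmax(0, matrix(rnorm(n_px * n_px, 0, noise_sd), n_px, n_px))
  }
  if (length(x) == 0) return(img)
  half <- ceiling(4 * sigma)
  for (i in seq_along(x)) {
    cx <- round(x[i]); cy <- round(y[i])
    xs <- max(0, cx - half):min(n_px - 1, cx + half)
    ys <- max(0, cy - half):min(n_px - 1, cy + half)
    gx <- exp(-((xs - x[i])^2) / (2 * sigma^2))
    gy <- exp(-((ys - y[i])^2) / (2 * sigma^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + outer(gy, gx)
  }
  img
}

#' Simulate a reseeding assay layout of two cell populations
#'
#' Emulates the spatial configurations seen when dissociated gastruloid
#' cells are reseeded on micro-discs: a `"mixed"` layout places both
#' populations uniformly over the disc (the salt-and-pepper state right
#' after reseeding), while `"sorted"` segregates them into disjoint
#' regions (the aggregated state after cell sorting).
#'
#' @param n_a,n_b Number of cells in populations `A` and `B`.
#' @param mode `"mixed"` or `"sorted"`.
#' @param arrangement For sorted layouts, `"halves"` puts each
#'   population in one half-disc; `"patches"` puts each into a disjoint
#'   circular patch.
#' @param markers Length-2 character, channel/marker names.
#' @param diameter_um,pixel_size_um,spot_sigma_px,background_noise_sd
#'   Rendering geometry, as in [colony_spec()].
#' @param seed Integer seed.
#' @return A `synthetic_colony` with channels `DAPI` plus the two markers.
#' @export
simulate_sorting_layout <- function(n_a, n_b,
                                    mode = c("mixed", "sorted"),
                                    arrangement = c("halves", "patches"),
                                    markers = c("A", "B"),
                                    diameter_um = 500, pixel_size_um = 2,
                                    spot_sigma_px = 3,
                                    background_noise_sd = 0.02,
                                    seed = 1L) {
  mode <- match.arg(mode)
  arrangement <- match.arg(arrangement)
  stop_if_not_scalar_number(n_a, "n_a", min = 1)
  stop_if_not_scalar_number(n_b, "n_b", min = 1)
  if (length(markers) != 2 || anyDuplicated(markers)) {
    abort("`markers` must be two distinct names.")
  }
  n_px <- ceiling(diameter_um / pixel_size_um)
  radius_px <- min(diameter_um / (2 * pixel_size_um), (n_px - 1) / 2)
  center <- (n_px - 1) / 2
  set.seed(as.integer(seed))

  sample_disc <- function(n, cx, cy, r) {
    rad <- r * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    list(x = cx + rad * cos(th), y = cy + rad * sin(th))
  }
  if (mode == "mixed") {
    pa <- sample_disc(n_a, center, center, radius_px)
    pb <- sample_disc(n_b, center, center, radius_px)
  } else if (arrangement == "halves") {
    # rejection-free: sample half-discs by folding the angle
    half_disc <- function(n, sign) {
      rad <- radius_px * sqrt(runif(n))
      th <- runif(n, -pi / 2, pi / 2)      # right half
      list(x = center + sign * rad * cos(th), y = center + rad * sin(th))
    }
    pa <- half_disc(n_a, +1)
    pb <- half_disc(n_b, -1)
  } else {
    patch_r <- radius_px / 3
    pa <- sample_disc(n_a, center + radius_px / 2, center, patch_r)
    pb <- sample_disc(n_b, center - radius_px / 2, center, patch_r)
  }

  cells <- data.frame(
    cell_id = seq_len(n_a + n_b),
    x_px = c(pa$x, pb$x), y_px = c(pa$y, pb$y),
    marker = rep(markers, c(n_a, n_b)),
    stringsAsFactors = FALSE)

  channels <- list(
    DAPI = render_spots(cells$x_px, cells$y_px, n_px, spot_sigma_px,
                        background_noise_sd))
  for (m in markers) {
    sub <- cells[cells$marker == m, ]
    channels[[m]] <- render_spots(sub$x_px, sub$y_px, n_px, spot_sigma_px,
                                  background_noise_sd)
  }
  structure(
    list(channels = channels, centroids = as_tibble(cells),
         spec = list(mode = mode, arrangement = arrangement,
                     diameter_um = diameter_um, pixel_size_um = pixel_size_um,
                     spot_sigma_px = spot_sigma_px, seed = as.integer(seed))),
    class = "synthetic_colony")
}

#' @export
print.synthetic_colony <- function(x, ...) {
  cat(sprintf("<synthetic_colony> %d channels (%s), %d centroids, %dx%d px\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              length(unique(x$centroids$cell_id)),
              nrow(x$channels[[1]]), ncol(x$channels[[1]])))
  invisible(x)
}
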