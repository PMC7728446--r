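# Radial intensity profiling of colony images.

#' Locate the colony center from the nuclear channel
#'
#' Thresholds the DAPI (or another) channel automatically (Otsu) and
#' returns the centroid of the foreground mask in 0-based pixel
#' coordinates (x = column, y = row).
#'
#' @param image Named list of channel matrices or a `synthetic_colony`.
#' @param channel Channel used for the mask, default `"DAPI"`.
#' @return Numeric `c(x, y)`.
#' @export
find_colony_center <- function(image, channel = "DAPI") {
  m <- get_channel(image, channel)
  thr <- otsu_threshold(m)
  mask <- m >= thr
  if (!any(mask)) abort("Empty foreground mask; cannot locate colony center.")
  grid <- pixel_grid(nrow(m), ncol(m))
  c(x = mean(grid$x[mask]), y = mean(grid$y[mask]))
}

#' Radial intensity profile of one channel
#'
#' Measures mean fluorescence intensity as a function of distance from
#' the colony center, using `n_rings` equally spaced concentric rings
#' spanning the colony radius. With `method = "annulus"` (default) each
#' value is the mean over an equal-width annulus; `method = "circle"`
#' samples only pixels within half a pixel of each ring's circumference,
#' mimicking plugin-style circle sampling.
#'
#' @param image Named list of channel matrices or a `synthetic_colony`.
#' @param channel Channel name to profile.
#' @param center `c(x, y)` in 0-based pixel coordinates; found
#'   automatically from the DAPI channel when `NULL`.
#' @param colony_radius_px Colony radius in pixels; defaults to half the
#'   smaller image dimension.
#' @param n_rings Number of rings (default 20).
#' @param method `"annulus"` or `"circle"` sampling.
#' @return Tibble with one row per ring: `marker`, `bin`,
#'   `radius_fraction` (outer edge of the ring, in (0, 1]),
#'   `intensity`, and `normalized = FALSE`.
#' @export
radial_profile <- function(image, channel, center = NULL,
                           colony_radius_px = NULL, n_rings = 20,
                           method = c("annulus", "circle")) {
  method <- match.arg(method)
  m <- get_channel(image, channel)
  stop_if_not_scalar_number(n_rings, "n_rings", min = 1)
  if (is.null(center)) center <- find_colony_center(image)
  if (length(center) != 2 || any(!is.finite(center))) {
    abort("`center` must be c(x, y).")
  }
  if (center[1] < 0 || center[1] > ncol(m) - 1 ||
      center[2] < 0 || center[2] > nrow(m) - 1) {
    abort("`center` must lie inside the image.")
  }
  if (is.null(colony_radius_px)) colony_radius_px <- min(dim(m)) / 2
  stop_if_not_scalar_number(colony_radius_px, "colony_radius_px", min = 1e-9)

  grid <- pixel_grid(nrow(m), ncol(m))
  r <- sqrt((grid$x - center[1])^2 + (grid$y - center[2])^2)

  intensity <- numeric(n_rings)
  for (k in seq_len(n_rings)) {
    if (method == "annulus") {
      lo <- (k - 1) / n_rings * colony_radius_px
      hi <- k / n_rings * colony_radius_px
      sel <- if (k == 1) r <= hi else r > lo & r <= hi
    } else {
      rk <- k / n_rings * colony_radius_px
      sel <- abs(r - rk) <= 0.5
    }
    if (!any(sel)) {
      abort(sprintf("Ring %d contains no pixels (radius too small for the grid).", k))
    }
    intensity[k] <- mean(m[sel])
  }

  tibble(marker = channel,
         bin = seq_len(n_rings),
         radius_fraction = seq_len(n_rings) / n_rings,
         intensity = intensity,
         normalized = FALSE)
}

#' Normalize a marker profile to the DAPI profile
#'
#' Pointwise ratio of a marker's radial profile to the DAPI profile,
#' matching the convention of reporting marker intensity relative to
#' nuclear density along the radius.
#'
#' @param marker_profile,dapi_profile Tibbles from [radial_profile()]
#'   with identical `radius_fraction` grids.
#' @param epsilon Nonnegative guard added to the DAPI denominator. With
#'   the default 0, a zero DAPI ring raises an error.
#' @return The marker profile with `intensity` replaced by the ratio and
#'   `normalized = TRUE`.
#' @export
normalize_to_dapi <- function(marker_profile, dapi_profile, epsilon = 0) {
  stop_if_not_scalar_number(epsilon, "epsilon", min = 0)
  if (nrow(marker_profile) != nrow(dapi_profile) ||
      !isTRUE(all.equal(marker_profile$radius_fraction,
                        dapi_profile$radius_fraction))) {
    abort("Marker and DAPI profiles must share the same radii.")
  }
  denom <- dapi_profile$intensity + epsilon
  if (any(denom == 0)) {
    abort(sprintf(
      "DAPI intensity is zero in ring(s) %s and epsilon = 0; supply a positive epsilon.",
      paste(which(denom == 0), collapse = ", ")))
  }
  out <- marker_profile
  out$intensity <- marker_profile$intensity / denom
  out$normalized <- TRUE
  out
}

#' Average radial profiles over colonies
#'
#' Per-ring arithmetic mean and standard error of the mean (SEM =
#' sd / sqrt(n)) across colonies, as used to summarise a marker over
#' many gastruloids. With a single profile the SEM is reported as 0
#' (with a warning), so single-colony runs stay well defined.
#'
#' @param profiles List of profile tibbles from [radial_profile()] (or
#'   [normalize_to_dapi()]) with identical marker and radii.
#' @return Tibble with `marker`, `bin`, `radius_fraction`,
#'   `mean_intensity`, `sem`, `n`.
#' @export
average_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0 ||
      inherits(profiles, "data.frame")) {
    abort("`profiles` must be a nonempty list of radial profiles.")
  }
  ref <- profiles[[1]]
  for (p in profiles[-1]) {
    if (!identical(p$marker[1], ref$marker[1]) ||
        !isTRUE(all.equal(p$radius_fraction, ref$radius_fraction))) {
      abort("All profiles must share the same marker and radii.")
    }
  }
  n <- length(profiles)
  vals <- vapply(profiles, function(p) p$intensity, numeric(nrow(ref)))
  vals <- matrix(vals, nrow = nrow(ref))
  if (n == 1) {
    warn("Single profile supplied; SEM reported as 0.")
    sem <- rep(0, nrow(ref))
  } else {
    sem <- apply(vals, 1, sd) / sqrt(n)
  }
  tibble(marker = ref$marker[1],
         bin = ref$bin,
         radius_fraction = ref$radius_fraction,
         mean_intensity = rowMeans(vals),
         sem = sem,
         n = n)
}
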