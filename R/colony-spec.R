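#' Specification of a synthetic micropatterned colony
#'
#' Describes a BMP4-differentiated micropatterned colony as concentric
#' marker rings on a circular ECM disc. The defaults emulate a 500 um
#' colony with the radial arrangement observed after 44 h of BMP4
#' treatment: SOX2+ ectoderm at the center, then T+ mesoderm, SOX17+
#' endoderm, and a CDX2+ extraembryonic-like ring at the edge, plus a
#' DAPI channel marking every nucleus. Default marker cell numbers are
#' proportioned to the reported marker fractions (roughly 61% SOX2,
#' 42% T, 18% SOX17, 32% CDX2 of nuclei, which sum to more than 100%
#' because some cells co-express markers).
#'
#' @param diameter_um Colony diameter in micrometers.
#' @param pixel_size_um Physical size of one pixel, micrometers.
#' @param ring_layout Named list mapping marker name to
#'   `c(inner, outer)` radius fractions of the colony radius. Rings may
#'   overlap between markers; within one marker `inner < outer` and both
#'   must lie in `[0, 1]`.
#' @param cells_per_marker Named integer vector, cells expressing each
#'   marker. Names must match `ring_layout`.
#' @param coexpression_rules Named numeric vector of probabilities; names
#'   are `"markerA:markerB"` pairs. A co-expressing cell is a single
#'   centroid listed under both markers and is placed in the first
#'   marker's ring.
#' @param spot_sigma_px Width (standard deviation, pixels) of the
#'   bell-shaped intensity bump rendered at each centroid.
#' @param background_noise_sd Standard deviation of additive background
#'   noise, in the same arbitrary intensity units as the spots
#'   (spot peak amplitude is 1).
#' @param radial_distribution Within-ring radial placement:
#'   `"area-uniform"` (uniform over annulus area, default) or
#'   `"radius-uniform"` (uniform in radius). The true within-ring
#'   distribution of each cell type is unknown, so it is a parameter.
#' @param seed Integer seed; a fixed seed makes the rendered colony
#'   bit-identical across runs.
#'
#' @return An object of class `colony_spec`.
#' @seealso [simulate_colony()], [simulate_sorting_layout()]
#' @export
#' @examples
#' spec <- colony_spec(cells_per_marker = c(SOX2 = 40, T = 30, SOX17 = 15, CDX2 = 25))
#' col <- simulate_colony(spec)
#' head(col$centroids)
colony_spec <- function(diameter_um = 500,
                        pixel_size_um = 2,
                        ring_layout = list(
                          SOX2  = c(0.00, 0.35),
                          T     = c(0.35, 0.60),
                          SOX17 = c(0.60, 0.80),
                          CDX2  = c(0.80, 1.00)),
                        cells_per_marker = c(SOX2 = 180, T = 125,
                                             SOX17 = 55, CDX2 = 95),
                        coexpression_rules = numeric(0),
                        spot_sigma_px = 3,
                        background_noise_sd = 0.02,
                        radial_distribution = c("area-uniform", "radius-uniform"),
                        seed = 1L) {
  stop_if_not_scalar_number(diameter_um, "diameter_um", min = 1)
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um", min = 1e-6)
  stop_if_not_scalar_number(spot_sigma_px, "spot_sigma_px", min = 1e-6)
  stop_if_not_scalar_number(background_noise_sd, "background_noise_sd", min = 0)
  radial_distribution <- match.arg(radial_distribution)

  if (!is.list(ring_layout) || is.null(names(ring_layout)) ||
      any(names(ring_layout) == "")) {
    abort("`ring_layout` must be a named list of c(inner, outer) fractions.")
  }
  for (marker in names(ring_layout)) {
    frac <- ring_layout[[marker]]
    if (length(frac) != 2 || any(!is.finite(frac)) ||
        any(frac < 0) || any(frac > 1) || frac[1] >= frac[2]) {
      abort(sprintf(
        "Ring for marker '%s' is impossible: need 0 <= inner < outer <= 1.",
        marker))
    }
  }
  if (is.null(names(cells_per_marker)) ||
      !all(names(cells_per_marker) %in% names(ring_layout))) {
    abort("`cells_per_marker` names must match `ring_layout` markers.")
  }
  if (any(cells_per_marker < 0) || any(cells_per_marker != round(cells_per_marker))) {
    abort("`cells_per_marker` must be nonnegative integers.")
  }
  if (length(coexpression_rules)) {
    if (is.null(names(coexpression_rules)) ||
        any(coexpression_rules < 0) || any(coexpression_rules > 1)) {
      abort("`coexpression_rules` must be named probabilities in [0, 1].")
    }
    pairs <- strsplit(names(coexpression_rules), ":", fixed = TRUE)
    ok <- vapply(pairs, function(p) {
      length(p) == 2 && all(p %in% names(ring_layout))
    }, logical(1))
    if (!all(ok)) {
      abort("`coexpression_rules` names must be 'markerA:markerB' pairs from ring_layout.")
    }
  }
  if ("DAPI" %in% names(ring_layout)) {
    abort("'DAPI' is reserved for the nuclear channel; do not list it as a marker.")
  }

  structure(
    list(diameter_um = diameter_um,
         pixel_size_um = pixel_size_um,
         ring_layout = ring_layout,
         cells_per_marker = cells_per_marker,
         coexpression_rules = coexpression_rules,
         spot_sigma_px = spot_sigma_px,
         background_noise_sd = background_noise_sd,
         radial_distribution = radial_distribution,
         seed = as.integer(seed)),
    class = "colony_spec")
}

#' @export
print.colony_spec <- function(x, ...) {
  cat(sprintf("<colony_spec> %g um disc, %g um/px, %d markers, %d cells\n",
              x$diameter_um, x$pixel_size_um, length(x$ring_layout),
              sum(x$cells_per_marker)))
  invisible(x)
}
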