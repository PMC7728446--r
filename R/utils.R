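# shared input checks and small numeric helpers

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)))
  }
  invisible(x)
}

#' Extract a channel matrix from an image-like object
#'
#' Accepts either a named list of equal-shaped intensity matrices or a
#' [synthetic_colony] object (whose `channels` element is such a list).
#' @noRd
get_channels <- function(image) {
  if (inherits(image, "synthetic_colony")) image <- image$channels
  if (!is.list(image) || is.null(names(image)) ||
      !all(vapply(image, is.matrix, logical(1)))) {
    abort("`image` must be a named list of intensity matrices (or a synthetic_colony).")
  }
  dims <- vapply(image, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    abort("All channels must share the same dimensions.")
  }
  if (any(vapply(image, function(m) any(m < 0), logical(1)))) {
    abort("Channel intensities must be nonnegative.")
  }
  image
}

get_channel <- function(image, channel) {
  ch <- get_channels(image)
  if (!channel %in% names(ch)) {
    abort(sprintf("Channel '%s' not found (have: %s).",
                  channel, paste(names(ch), collapse = ", ")))
  }
  ch[[channel]]
}

# pixel-center coordinate grids, 0-based, x = column, y = row
pixel_grid <- function(nrow, ncol) {
  list(x = matrix(rep(seq_len(ncol) - 1, each = nrow), nrow = nrow),
       y = matrix(rep(seq_len(nrow) - 1, times = ncol), nrow = nrow))
}

#' Otsu threshold of an intensity matrix
#'
#' Thin wrapper around [EBImage::otsu()] on the matrix rescaled to [0, 1].
#' @noRd
otsu_threshold <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (m - rng[1]) / diff(rng)
  EBImage::otsu(scaled, range = c(0, 1)) * diff(rng) + rng[1]
}
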