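# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' Tidy a composition table into long format
#' @param x A `composition_table`.
#' @param ... Unused.
#' @return Tibble with `cluster`, `label`, `fraction`.
#' @method tidy composition_table
#' @export
tidy.composition_table <- function(x, ...) {
  m <- unclass(x)
  names(dimnames(m)) <- c("cluster", "label")
  as_tibble(as.data.frame.table(m, responseName = "fraction")) |>
    dplyr::mutate(cluster = as.character(.data$cluster),
                  label = as.character(.data$label))
}

#' Tidy a permutation-test result
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with `cluster`, `label`, `observed_fraction`,
#'   `p_value`, `significant`.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  obs <- tidy.composition_table(x$observed) |>
    dplyr::rename(observed_fraction = "fraction")
  pm <- x$p_values
  names(dimnames(pm)) <- c("cluster", "label")
  pv <- as_tibble(as.data.frame.table(pm, responseName = "p_value")) |>
    dplyr::mutate(cluster = as.character(.data$cluster),
                  label = as.character(.data$label))
  dplyr::left_join(obs, pv, by = c("cluster", "label")) |>
    dplyr::mutate(significant = .data$p_value <= x$alpha)
}

#' One-row summary of a permutation-test result
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble with `n_clusters`, `n_labels`, `B`, `alpha`,
#'   `n_significant`, `min_p`.
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(n_clusters = nrow(x$p_values), n_labels = ncol(x$p_values),
         B = x$B, alpha = x$alpha,
         n_significant = sum(x$significant), min_p = min(x$p_values))
}

#' Tidy a prediction-score matrix into long format
#' @param x A `prediction_scores` matrix.
#' @param ... Unused.
#' @return Tibble with `cell_id`, `label`, `score`.
#' @method tidy prediction_scores
#' @export
tidy.prediction_scores <- function(x, ...) {
  m <- unclass(x)
  names(dimnames(m)) <- c("cell_id", "label")
  as_tibble(as.data.frame.table(m, responseName = "score")) |>
    dplyr::mutate(cell_id = as.character(.data$cell_id),
                  label = as.character(.data$label))
}

#' Tidy a diffusion-map result
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return Tibble with `cell_id` and one column per diffusion component.
#' @method tidy diffusion_result
#' @export
tidy.diffusion_result <- function(x, ...) {
  dplyr::bind_cols(tibble(cell_id = rownames(x$components)),
                   as_tibble(x$components))
}

#' One-row summary of a diffusion-map result
#' @param x A `diffusion_result`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `knn`, `sigma`, `n_dc`,
#'   `leading_eigenvalue`, `lambda_2`, `n_graph_components`.
#' @method glance diffusion_result
#' @export
glance.diffusion_result <- function(x, ...) {
  tibble(n_cells = nrow(x$transition), knn = x$params$knn,
         sigma = x$params$sigma, n_dc = ncol(x$components),
         leading_eigenvalue = x$leading_eigenvalue,
         lambda_2 = x$eigenvalues[1],
         n_graph_components = x$n_components_graph)
}

#' Plot averaged radial profiles
#'
#' Mean intensity against radius fraction with an SEM ribbon, one line
#' per marker — the standard presentation of marker intensity along the
#' colony radius.
#'
#' @param profiles Tibble from [average_profiles()], or several bound
#'   together (`dplyr::bind_rows`).
#' @return A ggplot object.
#' @export
plot_radial_profiles <- function(profiles) {
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$radius_fraction,
                               y = .data$mean_intensity,
                               colour = .data$marker, fill = .data$marker)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_intensity - .data$sem,
                                      ymax = .data$mean_intensity + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Radius fraction", y = "Mean intensity (per ring)") +
    ggplot2::theme_minimal()
}

#' @method autoplot density_map
#' @export
autoplot.density_map <- function(object, ...) {
  df <- as.data.frame.table(unclass(object), responseName = "density")
  df$x <- as.integer(df$Var2) - 1
  df$y <- as.integer(df$Var1) - 1
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  fill = "Expected cells / px") +
    ggplot2::theme_minimal()
}

#' @method autoplot composition_table
#' @export
autoplot.composition_table <- function(object, ...) {
  ggplot2::ggplot(tidy.composition_table(object),
                  ggplot2::aes(x = .data$cluster, y = .data$fraction,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Query cluster", y = "Fraction of cells",
                  fill = "Predicted label") +
    ggplot2::theme_minimal()
}

#' @method autoplot permutation_result
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tidy.permutation_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$cluster,
                                   fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$significant, , drop = FALSE],
                        shape = 8, size = 2) +
    ggplot2::labs(x = "Transferred label", y = "Query cluster",
                  fill = "-log10 p") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot diffusion_result
#' @export
autoplot.diffusion_result <- function(object, ...) {
  df <- tidy.diffusion_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$DC1, y = .data$DC2)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::theme_minimal()
}

#' @method autoplot synthetic_colony
#' @export
autoplot.synthetic_colony <- function(object, channel = NULL, ...) {
  ch <- if (is.null(channel)) names(object$channels) else channel
  dfs <- lapply(ch, function(nm) {
    m <- object$channels[[nm]]
    df <- as.data.frame.table(m, responseName = "intensity")
    df$x <- as.integer(df$Var2) - 1
    df$y <- as.integer(df$Var1) - 1
    df$channel <- nm
    df
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
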