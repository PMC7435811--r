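#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile facet_wrap labs scale_fill_gradient theme_minimal
#' @export
ggplot2::autoplot

#' Plot a gait histogram's per-axis bin counts
#'
#' @param object A [build_histogram()] result.
#' @param ... Unused.
#' @return A ggplot: bin counts as columns, one facet per axis.
#' @export
autoplot.gait_histogram <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("x", "y", "z"),
                            names_to = "axis", values_to = "count")
  mid <- (df$lo + df$hi) / 2
  ggplot(df, aes(x = mid, y = .data$count)) +
    geom_col(width = (object$hi[1L] - object$lo[1L]) * 0.9,
             fill = "steelblue") +
    facet_wrap(~axis, ncol = 1L) +
    labs(x = "directional value (1 + arcsin of axis ratio)", y = "count",
         title = sprintf("%s directional histogram",
                         attr(object, "sensor_kind"))) +
    theme_minimal()
}

#' Plot classification accuracy across histogram bin counts
#'
#' @param object A [sweep_bins()] result.
#' @param ... Unused.
#' @return A ggplot of accuracy versus bin count.
#' @export
autoplot.bin_sweep <- function(object, ...) {
  ggplot(tibble::as_tibble(object), aes(x = .data$n_bins, y = .data$accuracy)) +
    geom_line(colour = "steelblue") +
    geom_point() +
    labs(x = "histogram bins per axis", y = "classification accuracy") +
    theme_minimal()
}

#' Plot a similarity-derived distance matrix as a heat map
#'
#' @param object A [similarity_distance_matrix()] result.
#' @param ... Unused.
#' @return A ggplot tile map of pairwise distances.
#' @export
autoplot.dist_matrix <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$distance <- object[cbind(df$i, df$j)]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$distance)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = "sample", y = "sample", fill = "1 - similarity") +
    theme_minimal()
}

#' Plot the cluster-by-placement composition of a clustering
#'
#' @param object A [cluster_samples()] result with placement labels.
#' @param ... Unused.
#' @return A ggplot tile map of the contingency table.
#' @export
autoplot.gait_clustering <- function(object, ...) {
  comp <- cluster_composition(object)
  df <- tidyr::pivot_longer(comp, cols = -"cluster",
                            names_to = "placement", values_to = "n")
  ggplot(df, aes(x = .data$placement, y = factor(.data$cluster),
                 fill = .data$n)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "placement label", y = "cluster", fill = "samples") +
    theme_minimal()
}
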