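#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Training-history plot
#'
#' Held-out accuracy and loss over training steps, the standard view of
#' whether the network has reached criterion.
#'
#' @param object a `dag_rnn`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dag_rnn <- function(object, ...) {
  d <- tidyr::pivot_longer(object$history,
                           c("loss", "holdout_accuracy"),
                           names_to = "metric")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "training step", y = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy-by-category plot
#'
#' @param object an `rnn_evaluation`.
#' @param ... unused.
#' @return a ggplot of per-category judgment accuracy with the chance line.
#' @export
autoplot.rnn_evaluation <- function(object, ...) {
  d <- dplyr::filter(object$by_category, !is.na(.data$category))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$category,
                                                     -.data$accuracy),
                                  y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "DAG category", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Posterior-over-DAGs plot
#'
#' @param object a `dag_posterior`.
#' @param n_top number of highest-posterior DAGs to show.
#' @param ... unused.
#' @return a ggplot of posterior mass per DAG.
#' @export
autoplot.dag_posterior <- function(object, n_top = 10, ...) {
  d <- dplyr::slice_max(object$dags, .data$posterior, n = n_top)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label,
                                                     .data$posterior),
                                  y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Line-attractor plot
#'
#' Fixed points along the judgment axis with their sigmoid readouts: the
#' false-to-true organization of the attractor.
#'
#' @param object a `line_attractor`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.line_attractor <- function(object, ...) {
  d <- tidy.line_attractor(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$projection, y = .data$output)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(
      title = sprintf("query %s → %s",
                      LETTERS[object$query$cause], LETTERS[object$query$effect]),
      x = "judgment-axis projection", y = "sigmoid readout") +
    ggplot2::theme_minimal()
}

#' Attractor-geometry heatmap
#'
#' Pairwise centroid distances between the per-query line attractors,
#' ordered so same-cause blocks are adjacent.
#'
#' @param object an `attractor_geometry`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.attractor_geometry <- function(object, ...) {
  D <- object$distances
  d <- tibble::as_tibble(as.data.frame.table(D, responseName = "distance"))
  names(d)[1:2] <- c("query1", "query2")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$query1, y = .data$query2,
                                  fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "centroid\ndistance") +
    ggplot2::theme_minimal()
}

#' Trajectory plot in common principal-component space
#'
#' @param object a `pca_projection`.
#' @param ... unused.
#' @return a ggplot of PC1 vs PC2 for every projected trajectory.
#' @export
autoplot.pca_projection <- function(object, ...) {
  d <- object$tidy
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                  group = .data$trajectory,
                                  colour = factor(.data$trajectory))) +
    ggplot2::geom_path() +
    ggplot2::labs(
      colour = "trajectory",
      x = sprintf("PC1 (%.0f%%)", 100 * object$variance_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$variance_explained[2])) +
    ggplot2::theme_minimal()
}
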