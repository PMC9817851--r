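# ggplot2 graphics for the main result types.

#' Party-size distribution by origin
#'
#' Box plot of per-follow party sizes for wild- versus sanctuary-born
#' focals.
#'
#' @param party Tibble from [build_party_table()].
#' @return A ggplot object.
#' @export
plot_party_size <- function(party) {
  ggplot2::ggplot(party, ggplot2::aes(x = .data$origin,
                                      y = .data$party_size,
                                      fill = .data$origin)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.alpha = 0.3) +
    ggplot2::labs(x = "origin of focal", y = "party size (incl. focal)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Node-metric distributions by origin
#'
#' Violin-and-box summaries of the five network metrics, split by origin,
#' optionally facetted by behaviour when a `behaviour` column is present.
#'
#' @param metrics Metrics tibble with an `origin` column (e.g. the
#'   `metrics` element of a pipeline network block, or [node_metrics()]
#'   output joined with demographics).
#' @return A ggplot object.
#' @export
plot_metric_distributions <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(cols = dplyr::any_of(NET_METRICS),
                        names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$origin,
                                          y = .data$value,
                                          fill = .data$origin)) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA) +
    ggplot2::geom_boxplot(width = 0.25, alpha = 0.8,
                          outlier.alpha = 0.3) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if ("behaviour" %in% names(long)) {
    p + ggplot2::facet_grid(behaviour ~ metric, scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(~metric, scales = "free_y")
  }
}

#' @describeIn node_permutation_test Null-distribution histogram with the
#'   observed statistic marked.
#' @param object A `perm_test`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.perm_test <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::geom_vline(xintercept = -object$observed, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s: observed %s difference vs permutation null",
                      object$metric, object$stat),
      subtitle = sprintf("p = %.4g (%d %s)", object$p_value, object$n_perm,
                         if (object$exhaustive) "assignments"
                         else "permutations"),
      x = sprintf("%s(%s) - %s(%s) under label permutation", object$stat,
                  object$levels[1], object$stat, object$levels[2]),
      y = "count") +
    ggplot2::theme_minimal()
}

#' @describeIn build_assoc_matrix Heat map of the association matrix
#'   (missing dyads blank).
#' @param object An `assoc_matrix`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.assoc_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(id_a = ids, id_b = ids) |>
    mutate(ai = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id_a, y = .data$id_b,
                                   fill = .data$ai)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste(attr(object, "index"), "AI")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
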