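#' Plot a gradient embedding
#'
#' Scatter of units in the space of two gradient components, colored by
#' network.
#'
#' @param object A `gradient_embedding` or `aligned_gradients`.
#' @param networks Optional length-units network labels for coloring.
#' @param components Length-2 component indices (default c(1, 2)).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gradient_embedding <- function(object, networks = NULL,
                                        components = c(1, 2), ...) {
  m <- object$components
  df <- tibble(x = m[, components[1]], y = m[, components[2]],
               network = networks %||% "unit")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, color = .data$network)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = paste0("gradient ", components[1]),
                  y = paste0("gradient ", components[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.gradient_embedding
#' @exportS3Method ggplot2::autoplot
autoplot.aligned_gradients <- autoplot.gradient_embedding

#' Plot a cluster-number quality scan
#'
#' SSE elbow curve with silhouette and Calinski-Harabasz panels; the chosen
#' k is marked.
#'
#' @param object A `state_quality_scan`.
#' @param ... Unused.
#' @return A ggplot object (facetted).
#' @exportS3Method ggplot2::autoplot
autoplot.state_quality_scan <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scan,
                              c("sse", "silhouette", "calinski_harabasz"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Plot per-subject temporal state metrics by group
#'
#' Boxplots of fractional occupancy, mean dwell time or transitions per
#' state, split by group.
#'
#' @param metrics Output of [temporal_metrics()] (per-subject rows).
#' @param subjects Tibble with `subject_id` and `group`.
#' @param metric One of `"fo"`, `"mdt_windows"`, `"mdt_seconds"`, `"nt"`.
#' @return A ggplot object.
#' @export
plot_state_metrics <- function(metrics, subjects, metric = "fo") {
  df <- dplyr::left_join(metrics, subjects[, c("subject_id", "group")],
                         by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$state), .data[[metric]],
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "state", y = metric) +
    ggplot2::theme_minimal()
}

#' Plot an LOOCV ROC curve
#'
#' @param object A `loocv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.loocv_report <- function(object, ...) {
  pts <- roc_points(object)
  ggplot2::ggplot(pts, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", object$metrics$auc)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
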