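#' Plot metric curves over the sparsity grid
#'
#' Line plot of per-threshold metric values, one facet per metric.  When
#' a manifest is supplied, curves are colored by group and a group-mean
#' ribbon is not drawn (individual subjects stay visible).
#'
#' @param curves Long tibble from [connectome_metrics()] /
#'   [cohort_metrics()].
#' @param manifest Optional manifest tibble with `subject_id` and `group`.
#' @param metrics Optional subset of metric names.
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(curves, manifest = NULL, metrics = NULL) {
  df <- dplyr::filter(curves, .data$scope == "global")
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  if (!is.null(manifest)) {
    df <- dplyr::inner_join(df, dplyr::select(manifest, "subject_id", "group"),
                            by = "subject_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$sparsity, y = .data$value,
      group = .data$subject_id, color = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$sparsity, y = .data$value, group = .data$subject_id))
  }
  p +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot group-comparison results
#'
#' Dot plot of the observed adjusted group difference (patients minus
#' controls) per metric, with significance after correction encoded by
#' shape and fill.
#'
#' @param stats Tibble from [compare_groups()].
#' @return A ggplot object.
#' @export
plot_group_differences <- function(stats) {
  df <- dplyr::mutate(stats, label = metric_variable_id(
    .data$modality, .data$band, .data$metric, .data$scope, .data$node))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$observed_stat, y = .data$label,
    color = .data$significant)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey50")) +
    ggplot2::labs(x = "adjusted group difference (patient - control)",
                  y = NULL, color = "significant") +
    ggplot2::theme_minimal()
}
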