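#' Plot metric curves across the sparsity grid
#'
#' @param object A `metric_curves` object.
#' @param metrics Optional character vector of global metrics to keep.
#' @param ... Unused.
#' @return A ggplot: one panel per global metric, value versus density.
#' @export
autoplot.metric_curves <- function(object, metrics = NULL, ...) {
  df <- object$global
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$density, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sparsity (density)", y = "metric value") +
    ggplot2::theme_minimal()
}

#' Plot module sizes of a partition
#'
#' @param object A `modular_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of module sizes, annotated with Q.
#' @export
autoplot.modular_partition <- function(object, ...) {
  df <- tibble::tibble(
    module = factor(seq_along(object$sizes)), size = object$sizes
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      title = sprintf("%d modules, Q = %.3f", object$n_modules, object$q),
      x = "module", y = "ROIs"
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of mean module-block edge counts by session
#'
#' @param module_counts Tidy tibble from [cohort_module_counts()].
#' @return A ggplot tile plot, one facet per session, cell = mean edge count
#'   for the module block across subjects.
#' @export
plot_module_counts <- function(module_counts) {
  df <- module_counts |>
    dplyr::group_by(.data$session, .data$module_a, .data$module_b) |>
    dplyr::summarise(mean_count = mean(.data$count), .groups = "drop")
  df2 <- dplyr::bind_rows(
    df,
    dplyr::filter(df, .data$module_a != .data$module_b) |>
      dplyr::rename(module_a = "module_b", module_b = "module_a")
  )
  ggplot2::ggplot(df2, ggplot2::aes(
    x = factor(.data$module_a), y = factor(.data$module_b),
    fill = .data$mean_count
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~session) +
    ggplot2::labs(x = "module", y = "module", fill = "mean edges") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
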