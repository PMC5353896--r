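#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-service provenance timings
#'
#' Horizontal bars of elapsed time per SERVICE invocation, coloured by
#' status and annotated with the number of solution rows returned.
#'
#' @param object A `query_provenance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.query_provenance <- function(object, ...) {
  df <- object$services
  df$invocation <- factor(sprintf("%d: %s", seq_len(nrow(df)), sub("^https?://", "", df$endpoint)),
                          levels = rev(sprintf("%d: %s", seq_len(nrow(df)), sub("^https?://", "", df$endpoint))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elapsed_ms, y = .data$invocation,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$result_count), hjust = -0.3, size = 3) +
    ggplot2::labs(x = "elapsed (ms)", y = NULL,
                  title = paste("Service provenance,", object$query_id)) +
    ggplot2::theme_minimal()
}

#' Plot endpoint availability statuses
#'
#' Latency per endpoint from an availability check, with down endpoints
#' flagged.
#'
#' @param statuses A status tibble from [check_availability()].
#' @return A ggplot object.
#' @export
plot_endpoint_status <- function(statuses) {
  df <- statuses
  df$state <- ifelse(df$up, "up", "down")
  df$latency_plot <- ifelse(is.na(df$latency_ms), 0, df$latency_ms)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$latency_plot,
                                   y = stats::reorder(.data$url, .data$latency_plot),
                                   fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#2c7fb8", down = "#d95f0e")) +
    ggplot2::labs(x = "latency (ms)", y = NULL, title = "Endpoint availability") +
    ggplot2::theme_minimal()
}
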