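# Metric-vs-N curves in the style of the channel-evaluation figures.

#' Plot performance metrics against ensemble size
#'
#' One panel per metric, one line per channel, log2-spaced N axis, with a
#' dashed marker at the reference ensemble size (default N = 240).
#'
#' @param report A `metrics_report` from [run_metric_vs_N()] (or its
#'   `summary` data frame).
#' @param metrics Metrics to draw, among `"r"`, `"war"`, `"dwt_ms"`, `"dnv"`.
#' @param n_mark Ensemble size to mark with a dashed vertical line.
#' @return A ggplot object.
#' @export
plot_metric_curves <- function(report, metrics = c("r", "war", "dwt_ms"),
                               n_mark = 240) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  }
  df <- if (inherits(report, "metrics_report")) report$summary else report
  metrics <- match.arg(metrics, c("r", "war", "dwt_ms", "dnv"),
                       several.ok = TRUE)
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(channel = df$channel, N = df$N, metric = m, value = df[[m]],
               stringsAsFactors = FALSE)
  }))
  long$metric <- factor(long$metric, levels = metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = N, y = value, colour = channel)) +
    ggplot2::geom_vline(xintercept = n_mark, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "ensemble size N", y = NULL, colour = "channel") +
    ggplot2::theme_minimal()
}
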