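#' @describeIn compute_asd plot the A_SD trace, optionally with a threshold
#'   line.
#' @param object an `asd_trace`.
#' @param threshold optional `asd_threshold` (or number) drawn as a dashed
#'   line.
#' @export
autoplot.asd_trace <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$start_time, y = .data$asd)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s)", y = expression(A[SD] ~ (mu * V)))
  if (!is.null(threshold)) {
    tval <- if (inherits(threshold, "asd_threshold")) threshold$value else threshold
    p <- p + ggplot2::geom_hline(yintercept = tval, linetype = "dashed")
  }
  p
}

#' @describeIn segment_trace plot segments as shaded high/low variability
#'   spans.
#' @param object a `segment_set`.
#' @param ... unused.
#' @export
autoplot.segment_set <- function(object, ...) {
  thr <- attr(object, "threshold")
  ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_time, xmax = .data$end_time,
                                    ymin = 0, ymax = 1, fill = .data$kind),
                       alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(HVP = "#D55E00", LVP = "#0072B2")) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  subtitle = sprintf("threshold T = %.3g uV", thr$value)) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
}

#' Plot group HVP metrics by condition
#'
#' Box-and-point summary of subject-level (channel-averaged) metric values by
#' condition, one panel per metric.
#'
#' @param per_subject tibble with `subject`, `condition` and metric columns
#'   (e.g. from [average_channels()]).
#' @param metrics metric columns to show.
#' @return A ggplot object.
#' @export
plot_hvp_metrics <- function(per_subject,
                             metrics = c("hvp_d", "hvp_a", "lvp_d", "hvp_r", "ratio")) {
  metrics <- intersect(metrics, names(per_subject))
  long <- tidyr::pivot_longer(per_subject, dplyr::all_of(metrics),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL)
}
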