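#' Plot the learning-rate x segmentation interaction of a CV report
#'
#' Mean fold accuracy (with +/- 1 sd error bars) against learning rate, one
#' line per segmentation mode, faceted by window length — the package's
#' analogue of the interaction figures: a low learning rate favours
#' overlapping windows, a high one does not.
#'
#' @param object A `cv_report` from [run_experiment()].
#' @param metric Metric column to draw (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, metric = "accuracy", ...) {
  g <- glance(object)
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sd")
  ggplot2::ggplot(g, ggplot2::aes(
    x = factor(.data$lr), y = .data[[mcol]],
    colour = .data$mode, group = .data$mode
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(0, .data[[mcol]] - .data[[scol]]),
      ymax = pmin(1, .data[[mcol]] + .data[[scol]])
    )) +
    ggplot2::facet_wrap(~window_seconds, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "learning rate", y = paste("mean fold", metric),
      colour = "segmentation"
    ) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap of selected features
#'
#' @param cormat Correlation matrix from [correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cormat) {
  df <- tibble::as_tibble(as.table(cormat), .name_repair = ~ c("a", "b", "r"))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot a few channels of a recording with the condition track
#'
#' @param rec A `fnirs_recording`.
#' @param channels Channel indices to draw.
#' @return A ggplot object.
#' @export
plot_recording <- function(rec, channels = 1:4) {
  stopifnot(inherits(rec, "fnirs_recording"))
  t_sec <- (seq_len(ncol(rec$data)) - 1) / rec$fs
  df <- purrr::map_dfr(channels, function(j) {
    tibble::tibble(
      time = t_sec, value = rec$data[j, ],
      channel = rec$channels$name[j]
    )
  })
  blocks <- task_runs(rec$condition_track)
  blocks$start_s <- (blocks$start - 1) / rec$fs
  blocks$end_s <- (blocks$end - 1) / rec$fs
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      data = blocks,
      ggplot2::aes(
        xmin = .data$start_s, xmax = .data$end_s,
        ymin = -Inf, ymax = Inf, fill = .data$label
      ),
      alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_line(ggplot2::aes(.data$time, .data$value), linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "time (s)", y = expression(Delta * "concentration (" * mu * "M)"),
      fill = "condition"
    ) +
    ggplot2::theme_minimal()
}
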