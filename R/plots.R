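#' @describeIn gadf Plot a GADF image as a raster with a diverging scale.
#' @param object A `gadf_image`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.gadf_image <- function(object, ...) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object)),
    col = seq_len(ncol(object))
  )
  df$value <- object[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), name = "sin(φi − φj)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = attr(object, "lead") %||% "GADF image",
      x = "j (later sample)", y = "i (earlier sample)"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn t2_monitor Plot the control chart: per-cycle T-squared on a
#'   log-friendly scale with the UCL and out-of-control cycles marked.
#' @param object A `t2_monitoring` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.t2_monitoring <- function(object, ...) {
  ucl <- attr(object, "ucl")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cycle_index, y = .data$t2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$out_of_control), size = 1.2) +
    ggplot2::geom_hline(yintercept = ucl, linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "steelblue", `TRUE` = "red"),
      name = "Out of control"
    ) +
    ggplot2::labs(
      x = "Cycle", y = expression(T^2),
      title = sprintf("Hotelling T² chart (UCL = %.2f)", ucl)
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' Plots the ROC curve of anomaly scores against ground-truth labels and
#' annotates the AUROC.
#'
#' @inheritParams auroc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  a <- auroc(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUROC = %.4f)", a)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn synthesize_stream Plot the leads of a stream with
#'   ground-truth R centres marked.
#' @param object An `ecg_stream`.
#' @param max_seconds Plot at most this many seconds from the start.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ecg_stream <- function(object, max_seconds = 10, ...) {
  n <- min(nrow(object$samples), ceiling(max_seconds * object$sample_rate))
  df <- tibble::as_tibble(as.data.frame(object$samples[seq_len(n), , drop = FALSE]))
  df$time <- (seq_len(n) - 1) / object$sample_rate
  long <- tidyr::pivot_longer(df, -"time", names_to = "lead", values_to = "mV")
  marks <- object$r_centers[object$r_centers <= n] / object$sample_rate
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$mV)) +
    ggplot2::geom_vline(xintercept = marks, colour = "grey80", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$lead)) +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (mV)") +
    ggplot2::theme_minimal()
}
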