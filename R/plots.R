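# ggplot2 autoplot methods for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.fc_duration_curve <- function(object, ...) {
  df <- tidy(object)
  sl <- attr(object, "loglog_slope")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$duration_seconds,
                                   y = .data$mean_rms)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "scan duration (s, log scale)",
      y = "mean RMS difference in Fisher z (log scale)",
      title = "Reproducibility vs scan duration",
      subtitle = sprintf("log-log slope = %.3f (sqrt-time law: -0.5)", sl)
    )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fc_removal <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$mean_icc,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(scrub_random = "#c0392b",
                                            truncate = "#2980b9")) +
    ggplot2::labs(x = "fraction of time points removed",
                  y = "mean ICC",
                  colour = NULL,
                  title = "Reliability under scrubbing vs truncation")
}

#' @exportS3Method ggplot2::autoplot
autoplot.fc_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice_a, y = .data$slice_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Similarity of group-mean connectomes") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.fc_icc_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_icc)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::labs(x = sprintf("per-ROI mean ICC (%s)", attr(object, "form")),
                  y = "ROIs",
                  title = "Distribution of regional reliability")
}

#' @exportS3Method ggplot2::autoplot
autoplot.fc_volume_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume_cm3,
                                   y = .data$mean_icc)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(ROI ~ volume ~ (cm^3) ~ ", log scale"),
      y = "mean ICC",
      title = "Reliability rises with region volume",
      subtitle = sprintf("Spearman rank correlation = %.2f",
                         attr(object, "rank_correlation"))
    )
}
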