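#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' Heat map of log10 power over time and (log-scaled) frequency.
#'
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- as_tibble(object)
  eps <- max(df$power) * 1e-12
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = log10(.data$power + eps))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "Time (s)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot a CSD map
#'
#' Depth x time heat map with sinks (negative) in blue and sources in red,
#' the field's usual convention.
#'
#' @param object A `csd_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csd_map <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s * 1000, .data$depth_um,
                                   fill = .data$csd)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "CSD (V/mm²)") +
    ggplot2::labs(x = "Time (ms)", y = "Depth (µm)") +
    ggplot2::theme_minimal()
}

#' Plot cue-aligned trials
#'
#' Heat map of per-trial dF/F (or band power) plus the group-mean trace,
#' split by outcome.
#'
#' @param object A `trial_aligned` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trial_aligned <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$dff,
                                   group = .data$trial,
                                   colour = .data$outcome)) +
    ggplot2::geom_line(alpha = 0.25) +
    ggplot2::stat_summary(ggplot2::aes(group = .data$outcome),
                          fun = mean, geom = "line", linewidth = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from cue onset (s)", y = "dF/F",
                  colour = "Outcome") +
    ggplot2::theme_minimal()
}

#' Plot real vs null fold AUCs
#'
#' @param object A `decoding_report` (ideally after [null_model()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_report <- function(object, ...) {
  df <- dplyr::mutate(object$fold_aucs, model = "real")
  if (!is.null(object$null)) {
    df <- dplyr::bind_rows(df,
      dplyr::mutate(object$null$null_fold_aucs, model = "null"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$model, .data$auc,
                                   colour = .data$model)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Held-out ROC-AUC") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Psychometric accuracy curve
#'
#' Percent correct (and percent omissions) versus cue length from a
#' [score_accuracy()] table.
#'
#' @param by_cue Output of [score_accuracy()] (or the `by_cue` table of
#'   [behavior_summary()]).
#' @return A ggplot.
#' @export
plot_psychometric <- function(by_cue) {
  ggplot2::ggplot(by_cue, ggplot2::aes(.data$cue_length_s, .data$pct_correct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "Cue length (s)", y = "% correct (responded trials)") +
    ggplot2::theme_minimal()
}
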