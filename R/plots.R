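#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_point
#'   geom_histogram geom_vline geom_hline labs facet_wrap scale_y_log10
#'   scale_y_discrete theme_minimal
NULL

#' @export
ggplot2::autoplot

state_factor <- function(s) factor(s, levels = rev(sleep_states()),
                                   labels = rev(c("Wake", "NREM", "REM")))

#' Plot a hypnogram
#'
#' Classic staircase plot of behavioral state over time.
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hypnogram <- function(object, ...) {
  el <- epoch_len_of(object)
  df <- tibble(hours = (object$epoch - 1) * el / 3600,
               state = state_factor(object$state))
  ggplot(df, aes(.data$hours, .data$state, group = 1)) +
    geom_step(linewidth = 0.3) +
    labs(x = "Time (h)", y = NULL) +
    theme_minimal()
}

#' @rdname autoplot.hypnogram
#' @param h A [hypnogram()].
#' @export
plot_hypnogram <- function(h, ...) autoplot.hypnogram(h, ...)

#' Histogram of ensemble prediction certainty
#'
#' @param pred A [predict.sleep_ensemble()] result.
#' @param threshold Uncertainty threshold line (default 0.9).
#' @return A ggplot.
#' @export
plot_certainty <- function(pred, threshold = 0.9) {
  ggplot(tibble(certainty = pred$certainty), aes(.data$certainty)) +
    geom_histogram(bins = 40, fill = "grey30") +
    geom_vline(xintercept = threshold, linetype = 2, colour = "red") +
    labs(x = "Mean modal-class probability", y = "Epochs") +
    theme_minimal()
}

#' Plot state-dependent normalized spectra
#'
#' @param object A [state_spectra()] tibble.
#' @param max_hz Upper frequency limit to display.
#' @param ... Unused.
#' @return A ggplot (log power axis, one panel per channel).
#' @export
autoplot.state_spectra <- function(object, max_hz = 30, ...) {
  df <- dplyr::filter(object, .data$frequency >= 0.5, .data$frequency <= max_hz)
  ggplot(df, aes(.data$frequency, .data$power_norm, colour = .data$state)) +
    geom_line() +
    scale_y_log10() +
    facet_wrap(~channel) +
    labs(x = "Frequency (Hz)", y = "Normalized power") +
    theme_minimal()
}

#' Plot the hourly slow-wave-activity timecourse
#'
#' @param object A [swa_timecourse()] tibble.
#' @param ... Unused.
#' @return A ggplot with the light-period mean (1.0) as a reference line.
#' @export
autoplot.swa_timecourse <- function(object, ...) {
  ggplot(object, aes(.data$hour, .data$swa)) +
    geom_hline(yintercept = 1, linetype = 3) +
    geom_line() +
    geom_point() +
    labs(x = "Light-period hour", y = "Normalized SWA") +
    theme_minimal()
}
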