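#' Plot the hotspot recurrence histogram
#'
#' @param x A `hotspot_recurrence` result.
#' @return A ggplot: number of foci by events per focus.
#' @export
plot_recurrence <- function(x) {
  ggplot2::ggplot(x$histogram,
                  ggplot2::aes(.data$events_per_focus, .data$n_foci)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = x$histogram$events_per_focus) +
    ggplot2::labs(x = "Events per focus", y = "Number of foci",
                  title = "Recurrence of microdomain Ca2+ transients") +
    ggplot2::theme_classic()
}

#' Plot filopodial length traces
#'
#' @param tracks A `filo_tracks` tibble.
#' @return A ggplot of length (um) over time, one line per filopodium.
#' @export
plot_length_traces <- function(tracks) {
  ggplot2::ggplot(tracks, ggplot2::aes(.data$time_s, .data$length_um,
                                       group = .data$filo_id,
                                       colour = factor(.data$filo_id))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "Time (s)", y = "Length (um)",
                  title = "Tracheal filopodial length traces") +
    ggplot2::theme_classic()
}

#' Plot the motility category breakdown
#'
#' @param metrics A `motility_metrics` result.
#' @return A ggplot bar chart of category fractions.
#' @export
plot_categories <- function(metrics) {
  ggplot2::ggplot(metrics$categories,
                  ggplot2::aes(.data$category, .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "Fraction of filopodia",
                  title = "Filopodium motility categories") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_onset_peak
#' @param object An `onset_peak_fit`.
#' @param ... Unused.
#' @export
autoplot.onset_peak_fit <- function(object, ...) plot_onset_peak(object)

#' Plot the onset-versus-peak regression
#'
#' @param x An `onset_peak_fit` from [onset_peak_regression()].
#' @return A ggplot: retraction onsets against paired peaks with the OLS
#'   line.
#' @export
plot_onset_peak <- function(x) {
  p <- ggplot2::ggplot(x$records,
                       ggplot2::aes(.data$paired_peak_time_s,
                                    .data$onset_time_s)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Ca2+ event peak time (s)",
                  y = "Retraction onset time (s)",
                  title = sprintf("Onset vs peak (R^2 = %.3f, n = %d)",
                                  x$r_squared, x$n)) +
    ggplot2::theme_classic()
  if (!x$insufficient) {
    p <- p + ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                                  colour = "firebrick")
  }
  p
}

#' Plot latency distributions by onset type
#'
#' @param records Coupling records from [pair_latencies()].
#' @return A ggplot histogram of latencies, faceted by onset type.
#' @export
plot_latencies <- function(records) {
  rec <- records[is.finite(records$latency_s), ]
  ggplot2::ggplot(rec, ggplot2::aes(.data$latency_s)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey30") +
    ggplot2::facet_wrap(~ .data$onset_type, scales = "free") +
    ggplot2::labs(x = "Peak-to-onset latency (s)", y = "Count",
                  title = "Event peak to motility-onset latencies") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
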