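#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the onset-versus-peak regression
#'
#' @param x An `onset_peak_fit` from [onset_peak_regression()].
#' @param ... Unused.
#' @return One row per coefficient with estimate, standard error, t and p.
#' @export
tidy.onset_peak_fit <- function(x, ...) {
  if (x$insufficient) {
    return(tibble(term = character(), estimate = numeric(),
                  std.error = numeric(), statistic = numeric(),
                  p.value = numeric()))
  }
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("(Intercept)", "peak_time_s"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname tidy.onset_peak_fit
#' @export
glance.onset_peak_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
         nobs = x$n, insufficient = x$insufficient)
}

#' Glance at a coupling summary
#'
#' @param x A `coupling_summary`.
#' @param ... Unused.
#' @return A one-row tibble with the headline coupling numbers.
#' @export
glance.coupling_summary <- function(x, ...) {
  tibble(
    fraction_tips_overlapping = x$fraction_tips_overlapping,
    n_tips = x$n_tips,
    retraction_latency_mean_s = x$retraction_latency$mean,
    retraction_latency_sem_s = x$retraction_latency$sem,
    n_retraction = x$retraction_latency$n,
    extension_interval_mean_s = x$extension_interval$mean,
    extension_interval_sem_s = x$extension_interval$sem,
    n_extension = x$extension_interval$n,
    r_squared = x$regression$r_squared,
    slope = x$regression$slope,
    intercept = x$regression$intercept,
    bystander_correlation = if (!is.null(x$bystander)) x$bystander$correlation else NA_real_)
}

#' Glance at an epoch comparison
#'
#' @param x An `epoch_comparison` from [compare_epochs()].
#' @param ... Unused.
#' @return A one-row tibble with the paired-test summary.
#' @export
glance.epoch_comparison <- function(x, ...) {
  tibble(n_preparations = nrow(x$per_prep), mean_diff_per_min = x$mean_diff,
         mean_pct_change = x$mean_pct_change, t_statistic = x$t_statistic,
         df = x$df, p_value = x$p_value, test_available = x$test_available)
}
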