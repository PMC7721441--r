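#' Compare event frequencies before and after bath application
#'
#' Splits each preparation's event times at `split_s` (typically the drug
#' application point, half way through the recording), computes events per
#' minute in each epoch, and tests the within-preparation change with a
#' paired t statistic computed from the textbook formula on the
#' per-preparation differences: `t = mean(d) / (sd(d) / sqrt(n))` with
#' `n - 1` degrees of freedom.
#'
#' @param event_times Data frame with columns `prep` (preparation id) and
#'   `time_s` (event peak times, seconds). Preparations with zero events
#'   still count if listed in `preps`.
#' @param split_s Epoch boundary, strictly inside the recording.
#' @param duration_s Recording duration, seconds.
#' @param preps Optional vector of preparation ids, to include
#'   preparations without any events.
#' @return List of class `epoch_comparison`: `per_prep` tibble (`prep`,
#'   `pre_per_min`, `post_per_min`, `diff_per_min`), `mean_diff`,
#'   `t_statistic`, `df`, `p_value`, `mean_pct_change`, and
#'   `test_available` (`FALSE`, with `NA` statistics, for a single
#'   preparation).
#' @export
compare_epochs <- function(event_times, split_s, duration_s, preps = NULL) {
  if (split_s <= 0 || split_s >= duration_s) {
    abort("`split_s` must lie strictly inside the recording.")
  }
  stopifnot(all(c("prep", "time_s") %in% names(event_times)))
  preps <- preps %||% sort(unique(event_times$prep))
  pre_min <- split_s / 60
  post_min <- (duration_s - split_s) / 60
  per_prep <- tibble(prep = preps) |>
    dplyr::left_join(
      event_times |>
        dplyr::summarise(n_pre = sum(.data$time_s < split_s),
                         n_post = sum(.data$time_s >= split_s),
                         .by = "prep"),
      by = "prep") |>
    dplyr::mutate(
      n_pre = tidyr::replace_na(.data$n_pre, 0L),
      n_post = tidyr::replace_na(.data$n_post, 0L),
      pre_per_min = .data$n_pre / pre_min,
      post_per_min = .data$n_post / post_min,
      diff_per_min = .data$post_per_min - .data$pre_per_min)
  n <- nrow(per_prep)
  d <- per_prep$diff_per_min
  test_available <- n >= 2
  t_stat <- if (!test_available) NA_real_
  else if (sd(d) > 0) mean(d) / (sd(d) / sqrt(n))
  else if (mean(d) == 0) 0        # no change anywhere: t is exactly 0
  else sign(mean(d)) * Inf
  p <- if (test_available) 2 * pt(-abs(t_stat), n - 1) else NA_real_
  pct <- per_prep$pre_per_min
  pct_change <- ifelse(pct > 0, 100 * per_prep$diff_per_min / pct, NA_real_)
  structure(
    list(per_prep = per_prep, mean_diff = mean(d),
         t_statistic = t_stat, df = if (test_available) n - 1 else NA_integer_,
         p_value = p, mean_pct_change = mean(pct_change, na.rm = TRUE),
         test_available = test_available, split_s = split_s),
    class = "epoch_comparison")
}

#' @export
print.epoch_comparison <- function(x, ...) {
  cat(sprintf(
    "<epoch_comparison> split at %gs, %d preparations: mean change %+.3g events/min (%+.3g%%)\n",
    x$split_s, nrow(x$per_prep), x$mean_diff, x$mean_pct_change))
  if (x$test_available) {
    cat(sprintf("  paired t = %.3f, df = %d, p = %.4g\n",
                x$t_statistic, x$df, x$p_value))
  } else {
    cat("  paired t-test unavailable (need >= 2 preparations with variation)\n")
  }
  invisible(x)
}
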