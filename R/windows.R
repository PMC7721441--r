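#' Count events in a grid of counting windows
#'
#' Tiles the field with side-to-side windows of `window_px` pixels (the
#' standard scheme tiles a 100 um x 100 um, 300 x 300 px crop into nine
#' 100 x 100 px windows), assigns every event to exactly one window by its
#' centroid, and reports per-window counts together with the field-wide
#' event frequency per minute. When the field is not an exact multiple of
#' the window size the residual margin is excluded and a message is
#' emitted; events whose centroid falls in the margin are dropped from the
#' counts. A centroid lying exactly on a window boundary is assigned to the
#' lower-index window.
#'
#' @param events A `ca_events` tibble from [detect_events()].
#' @param field_px Integer `(height, width)` of the field in pixels.
#' @param window_px Integer `(height, width)` of one window in pixels.
#' @param duration_s Recording duration in seconds.
#' @return A list of class `window_counts`: `counts` tibble
#'   (`window_row`, `window_col`, `window_id`, `n_events`), `grid_shape`,
#'   `window_px`, `total_count`, `frequency_per_min`.
#' @examples
#' count_events_in_windows(detect_events(compute_dff(
#'   movie_stack(array(100, c(4, 6, 6)), 0.3, 1/3))),
#'   field_px = c(6, 6), window_px = c(3, 3), duration_s = 1.2)
#' @export
count_events_in_windows <- function(events, field_px, window_px, duration_s) {
  grid <- field_px %/% window_px
  if (any(field_px %% window_px != 0)) {
    inform(sprintf(
      "field (%d x %d px) is not a multiple of the window (%d x %d px); residual margin excluded.",
      field_px[1], field_px[2], window_px[1], window_px[2]))
  }
  if (any(grid < 1)) abort("window larger than the field.")

  # boundary rule: index = ceil(p / h) - 1 puts an exact-boundary centroid
  # in the lower-index window; centroids are 0-based pixel coordinates
  win_index <- function(p, h) pmax(0, ceiling(p / h) - 1)
  assigned <- tibble(window_row = integer(), window_col = integer())
  n_margin <- 0L
  if (nrow(events) > 0) {
    wr <- win_index(events$centroid_row - 1, window_px[1])
    wc <- win_index(events$centroid_col - 1, window_px[2])
    inside <- wr < grid[1] & wc < grid[2]
    n_margin <- sum(!inside)
    if (n_margin > 0) {
      inform(sprintf("%d event(s) in the excluded margin.", n_margin))
    }
    assigned <- tibble(window_row = as.integer(wr[inside]),
                       window_col = as.integer(wc[inside]))
  }
  counts <- tidyr::expand_grid(window_row = 0:(grid[1] - 1),
                               window_col = 0:(grid[2] - 1)) |>
    dplyr::left_join(dplyr::count(assigned, .data$window_row, .data$window_col),
                     by = c("window_row", "window_col")) |>
    dplyr::mutate(n_events = tidyr::replace_na(.data$n, 0L), n = NULL,
                  window_id = .data$window_row * grid[2] + .data$window_col + 1L)
  total <- sum(counts$n_events)
  structure(
    list(counts = counts, grid_shape = as.integer(grid),
         window_px = as.integer(window_px), total_count = total,
         n_margin_events = n_margin,
         frequency_per_min = total / (duration_s / 60)),
    class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("<window_counts> %d x %d windows of %d x %d px: %d events, %.3g events/min\n",
              x$grid_shape[1], x$grid_shape[2], x$window_px[1], x$window_px[2],
              x$total_count, x$frequency_per_min))
  invisible(x)
}
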