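#' Group events into recurrence foci (hotspots)
#'
#' Microdomain transients recur at fixed spatial foci. This clusters event
#' centroids by single linkage with a merge radius: two events belong to
#' the same focus if they are connected by a chain of centroids each within
#' `merge_radius_um` of the next. Returns the per-focus event counts and
#' the recurrence histogram (how many foci produced 1, 2, 3, ... events).
#'
#' @param events A `ca_events` tibble.
#' @param merge_radius_um Single-linkage merge radius in micrometres.
#' @return A list of class `hotspot_recurrence`: `events` (input with
#'   `hotspot_id` filled in), `foci` (per-focus centroid and event count),
#'   `histogram` tibble (`events_per_focus`, `n_foci`).
#' @export
hotspot_recurrence <- function(events, merge_radius_um = 3) {
  if (merge_radius_um <= 0) abort("`merge_radius_um` must be > 0.")
  n <- nrow(events)
  if (n == 0) {
    return(structure(list(events = events,
                          foci = tibble(hotspot_id = integer(), x_um = numeric(),
                                        y_um = numeric(), n_events = integer()),
                          histogram = tibble(events_per_focus = integer(),
                                             n_foci = integer())),
                     class = "hotspot_recurrence"))
  }
  memb <- if (n == 1) 1L else {
    hc <- stats::hclust(stats::dist(cbind(events$x_um, events$y_um)),
                        method = "single")
    stats::cutree(hc, h = merge_radius_um)
  }
  # relabel foci in order of first appearance
  memb <- as.integer(factor(memb, levels = unique(memb)))
  events$hotspot_id <- memb
  foci <- events |>
    dplyr::summarise(x_um = mean(.data$x_um), y_um = mean(.data$y_um),
                     n_events = dplyr::n(), .by = "hotspot_id")
  histogram <- foci |>
    dplyr::count(events_per_focus = .data$n_events, name = "n_foci") |>
    dplyr::arrange(.data$events_per_focus)
  structure(list(events = events, foci = foci, histogram = histogram),
            class = "hotspot_recurrence")
}

#' @export
print.hotspot_recurrence <- function(x, ...) {
  cat(sprintf("<hotspot_recurrence> %d events at %d foci\n",
              nrow(x$events), nrow(x$foci)))
  print(x$histogram)
  invisible(x)
}
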