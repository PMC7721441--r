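#' Match coincident events across two imaging channels
#'
#' For dual-indicator recordings (e.g. a green and a red Ca2+ sensor in
#' neighbouring astrocytes), finds one-to-one pairs of events that coincide
#' in space and time: candidate pairs must have centroids within
#' `max_centroid_dist_um` and peaks within `max_peak_dt_s`, and are matched
#' greedily in ascending order of the normalized spatiotemporal distance
#' `sqrt((d/d_max)^2 + (dt/dt_max)^2)`, so each event joins at most one
#' pair.
#'
#' @param events_a,events_b `ca_events` tibbles from movies with identical
#'   calibration.
#' @param max_centroid_dist_um Maximum centroid separation, um.
#' @param max_peak_dt_s Maximum peak-time difference, seconds.
#' @return Tibble of pairs: `event_id_a`, `event_id_b`, `dist_um`, `dt_s`,
#'   `score`.
#' @export
cross_channel_coincidence <- function(events_a, events_b,
                                      max_centroid_dist_um = 5,
                                      max_peak_dt_s = 2) {
  cal <- function(e) c(attr(e, "frame_interval_s") %||% NA,
                       attr(e, "pixel_size_um") %||% NA)
  if (!isTRUE(all.equal(cal(events_a), cal(events_b)))) {
    abort("channel calibrations differ; events must come from identically calibrated movies.")
  }
  empty <- tibble(event_id_a = integer(), event_id_b = integer(),
                  dist_um = numeric(), dt_s = numeric(), score = numeric())
  if (nrow(events_a) == 0 || nrow(events_b) == 0) return(empty)

  cand <- tidyr::expand_grid(ia = seq_len(nrow(events_a)),
                             ib = seq_len(nrow(events_b))) |>
    dplyr::mutate(
      dist_um = sqrt((events_a$x_um[.data$ia] - events_b$x_um[.data$ib])^2 +
                     (events_a$y_um[.data$ia] - events_b$y_um[.data$ib])^2),
      dt_s = abs(events_a$peak_time_s[.data$ia] - events_b$peak_time_s[.data$ib])) |>
    dplyr::filter(.data$dist_um <= max_centroid_dist_um,
                  .data$dt_s <= max_peak_dt_s) |>
    dplyr::mutate(score = sqrt((.data$dist_um / max_centroid_dist_um)^2 +
                               (.data$dt_s / max_peak_dt_s)^2)) |>
    dplyr::arrange(.data$score, .data$ia, .data$ib)
  if (nrow(cand) == 0) return(empty)

  used_a <- logical(nrow(events_a)); used_b <- logical(nrow(events_b))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[i]] && !used_b[cand$ib[i]]) {
      keep[i] <- TRUE
      used_a[cand$ia[i]] <- TRUE
      used_b[cand$ib[i]] <- TRUE
    }
  }
  cand[keep, ] |>
    dplyr::transmute(event_id_a = events_a$event_id[.data$ia],
                     event_id_b = events_b$event_id[.data$ib],
                     dist_um = .data$dist_um, dt_s = .data$dt_s,
                     score = .data$score)
}
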