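#' Detect microdomain Ca2+ transients
#'
#' Segments a dF/F0 movie into spatiotemporal events. Voxels at or above
#' the cutoff (the detection threshold is inclusive: a transient peaking at
#' exactly the cutoff is reported) are grouped into connected components
#' using the 4-neighbourhood in space and same-pixel adjacency across
#' consecutive frames. Components shorter than `min_duration_frames` or
#' whose spatial footprint (the union of member pixels over the event's
#' lifetime, its maximum domain) is smaller than `min_area_px` are
#' discarded. Each surviving component is then measured on its
#' footprint-averaged trace ([measure_event()]); when `confirm_mean`
#' is `TRUE` (default) the event is kept only if that trace's peak also
#' reaches the cutoff, mirroring confirmation of candidate events on an
#' ROI-mean trace.
#'
#' @param dff A `dff_movie` from [compute_dff()].
#' @param cutoff_pct Detection cutoff in percent dF/F0 (default 5).
#' @param min_duration_frames Minimum event duration in frames.
#' @param min_area_px Minimum footprint area in pixels.
#' @param smooth_sigma_px If `> 0`, Gaussian-smooth each frame spatially by
#'   this sigma (pixels) before thresholding (measurement still uses the
#'   unsmoothed movie). Off by default.
#' @param close_time_gaps Bridge sub-threshold gaps of up to this many
#'   frames at pixels that are suprathreshold on both sides, so noise
#'   flicker at a transient's rise and fall does not split one event into
#'   several. On noise-free input this changes nothing (waveforms are
#'   unimodal). Set 0 to disable.
#' @param confirm_mean Require the footprint-averaged peak to reach the
#'   cutoff.
#' @return A tibble of class `ca_events`, one row per event, sorted by
#'   `peak_time_s` (ties by centroid row then column): ids, frames, peak
#'   time, centroid (um), `amplitude_pct`, `fwhm_s` (NA when censored),
#'   censoring and edge flags, footprint area, plus list-columns
#'   `footprint` (two-column matrix of pixel rows/cols) and
#'   `aligned_trace` (41 samples, peak at index 21, i.e. t = 20 of t =
#'   0..40). Calibration is carried in attributes.
#' @export
detect_events <- function(dff, cutoff_pct = 5, min_duration_frames = 2,
                          min_area_px = 4, smooth_sigma_px = 0,
                          close_time_gaps = 1, confirm_mean = TRUE) {
  stopifnot(inherits(dff, "dff_movie"))
  if (cutoff_pct <= 0) abort("`cutoff_pct` must be > 0.")
  d <- dim(dff$dff)
  vol <- dff$dff
  if (smooth_sigma_px > 0) {
    for (k in seq_len(d[1])) vol[k, , ] <- gauss_smooth_2d(vol[k, , ], smooth_sigma_px)
  }
  thr <- cutoff_pct / 100 - 1e-12    # inclusive cutoff, robust to fp rounding
  mask <- !is.na(vol) & vol >= thr
  if (close_time_gaps > 0 && d[1] > 2) {
    for (g in seq_len(close_time_gaps)) {
      lead <- mask[c((1 + g):d[1], rep(d[1], g)), , , drop = FALSE]
      lag <- mask[c(rep(1, g), 1:(d[1] - g)), , , drop = FALSE]
      mask <- mask | (lead & lag)
    }
  }
  idx <- which(mask)
  events <- empty_events()
  if (length(idx)) {
    co <- arrayInd(idx, d)                       # frame, row, col
    memb <- sparse_components(co, stencil_spatiotemporal(), d)
    rows <- list()
    for (m in split(seq_along(memb), memb)) {
      frames <- sort(unique(co[m, 1]))
      fpx <- unique(co[m, 2:3, drop = FALSE])
      if (length(frames) < min_duration_frames || nrow(fpx) < min_area_px) next
      meas <- measure_event(dff, fpx, frames)
      if (confirm_mean && meas$amplitude_pct < cutoff_pct - 1e-9) next
      rows[[length(rows) + 1L]] <- tibble(
        onset_frame = frames[1], offset_frame = frames[length(frames)],
        peak_frame = meas$peak_frame,
        peak_time_s = (meas$peak_frame - 1) * dff$frame_interval_s,
        centroid_row = mean(fpx[, 1]), centroid_col = mean(fpx[, 2]),
        x_um = px_to_um(mean(fpx[, 2]), dff$pixel_size_um),
        y_um = px_to_um(mean(fpx[, 1]), dff$pixel_size_um),
        amplitude_pct = meas$amplitude_pct, fwhm_s = meas$fwhm_s,
        fwhm_censored = meas$fwhm_censored, edge_flagged = meas$edge_flagged,
        area_px = nrow(fpx),
        duration_s = length(frames) * dff$frame_interval_s,
        footprint = list(fpx), aligned_trace = list(meas$aligned_trace))
    }
    if (length(rows)) {
      events <- dplyr::bind_rows(rows) |>
        dplyr::arrange(.data$peak_time_s, .data$centroid_row, .data$centroid_col) |>
        dplyr::mutate(event_id = dplyr::row_number(), hotspot_id = NA_integer_,
                      .before = 1)
    }
  }
  structure(events, class = c("ca_events", class(events)),
            frame_interval_s = dff$frame_interval_s,
            pixel_size_um = dff$pixel_size_um, cutoff_pct = cutoff_pct)
}

empty_events <- function() {
  tibble(event_id = integer(), hotspot_id = integer(),
         onset_frame = integer(), offset_frame = integer(),
         peak_frame = integer(), peak_time_s = numeric(),
         centroid_row = numeric(), centroid_col = numeric(),
         x_um = numeric(), y_um = numeric(), amplitude_pct = numeric(),
         fwhm_s = numeric(), fwhm_censored = logical(),
         edge_flagged = logical(), area_px = integer(),
         duration_s = numeric(), footprint = list(), aligned_trace = list())
}

#' Measure one event on its footprint-averaged trace
#'
#' Averages dF/F0 over the event's footprint pixels at every frame of the
#' movie, then reports the amplitude (peak of that trace within the event's
#' frames, in percent), the FWHM from linear-interpolated half-maximum
#' crossings around the peak (censored, with `fwhm_s = NA`, when the trace
#' never falls below half maximum inside the recording on one side), and
#' the 41-sample aligned trace: frames `peak - 20 .. peak + 20`, so the
#' peak sits at sample t = 20 of t = 0..40. Events whose peak is within 20
#' frames of either end of the movie are padded with the boundary value and
#' flagged.
#'
#' @param dff A `dff_movie`.
#' @param footprint Two-column matrix of (row, col) footprint pixels.
#' @param frames Integer vector of the event's frames.
#' @return List with `amplitude_pct`, `fwhm_s`, `fwhm_censored`,
#'   `peak_frame`, `aligned_trace` (percent units), `edge_flagged`, and the
#'   full footprint-averaged `trace_pct`.
#' @export
measure_event <- function(dff, footprint, frames) {
  stopifnot(nrow(footprint) > 0)
  d <- dim(dff$dff)
  if (any(frames < 1 | frames > d[1])) abort("`frames` outside the movie.")
  acc <- numeric(d[1])
  for (i in seq_len(nrow(footprint))) {
    acc <- acc + dff$dff[, footprint[i, 1], footprint[i, 2]]
  }
  trace <- acc / nrow(footprint) * 100   # percent

  peak_frame <- frames[which.max(trace[frames])]
  amplitude_pct <- trace[peak_frame]

  fw <- trace_fwhm(trace, dff$frame_interval_s, peak_index = peak_frame)
  window <- (peak_frame - 20):(peak_frame + 20)
  clamped <- pmin(pmax(window, 1L), d[1])
  aligned <- trace[clamped]
  list(amplitude_pct = amplitude_pct, fwhm_s = fw$fwhm_s,
       fwhm_censored = fw$left_censored || fw$right_censored,
       peak_frame = peak_frame, aligned_trace = aligned,
       edge_flagged = any(window != clamped), trace_pct = trace)
}

# Separable Gaussian smoothing of a matrix (reflected edges).
gauss_smooth_2d <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  pad_filter <- function(v) {
    vp <- c(rev(v[seq_len(r)]), v, rev(v[(length(v) - r + 1):length(v)]))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  m1 <- apply(m, 2, pad_filter)
  t(apply(m1, 1, pad_filter))
}
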