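range_key <- function(r, c) r * 1e6 + c

# Pixel-set keys of one event footprint.
footprint_keys <- function(footprint) {
  range_key(footprint[, 1], footprint[, 2])
}

# Tip pixel keys per frame for one filopodium.
tip_keys <- function(track, ps) {
  range_key(um_to_px(track$tip_y_um, ps), um_to_px(track$tip_x_um, ps))
}

shared_pixel_size <- function(events, tracks) {
  ps <- attr(events, "pixel_size_um") %||% attr(tracks, "pixel_size_um")
  if (is.null(ps) || !is.finite(ps)) {
    abort("no pixel size calibration found on `events` or `tracks`.")
  }
  ps
}

#' Test tip-in-domain overlap between events and filopodia
#'
#' Overlap is defined as the filopodial tip falling, at any frame, within
#' the maximum size of the event's domain: the union of the event's
#' suprathreshold pixels over its lifetime. The tip position (um) is mapped
#' to the pixel whose centre is nearest and membership in the footprint
#' pixel set is tested per frame; the entry time is the first frame at
#' which the tip is inside.
#'
#' @param events A `ca_events` tibble.
#' @param tracks A `filo_tracks` tibble (same calibration).
#' @return Tibble with one row per (event, filopodium) pair: `event_id`,
#'   `filo_id`, `overlap`, `entry_time_s` (`NA` when no overlap).
#' @export
test_overlap <- function(events, tracks) {
  out <- tibble(event_id = integer(), filo_id = integer(),
                overlap = logical(), entry_time_s = numeric())
  if (nrow(events) == 0 || nrow(tracks) == 0) return(out)
  ps <- shared_pixel_size(events, tracks)
  per_filo <- split(tracks, tracks$filo_id)
  rows <- list()
  for (i in seq_len(nrow(events))) {
    keys <- footprint_keys(events$footprint[[i]])
    for (tr in per_filo) {
      inside <- tip_keys(tr, ps) %in% keys
      rows[[length(rows) + 1L]] <- tibble(
        event_id = events$event_id[i], filo_id = tr$filo_id[1],
        overlap = any(inside),
        entry_time_s = if (any(inside)) tr$time_s[which(inside)[1]] else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Pair motility onsets with preceding Ca2+ event peaks
#'
#' For every onset of every filopodium that overlaps at least one event,
#' finds the nearest preceding event peak within `max_lag_s` among the
#' events whose domain contains that filopodium's tip, and records the
#' latency `onset - peak`. If two candidate events share the same peak
#' time, the larger-amplitude event is paired. Onsets with no qualifying
#' peak are recorded with a null pairing.
#'
#' @param events A `ca_events` tibble.
#' @param tracks A `filo_tracks` tibble.
#' @param onsets Onset table from [detect_motility_onsets()]; computed with
#'   defaults when missing.
#' @param overlaps Overlap table from [test_overlap()]; computed when
#'   missing.
#' @param max_lag_s Maximum peak-to-onset lag considered, seconds.
#' @return Tibble of coupling records: `event_id` (`NA` for unpaired),
#'   `filo_id`, `onset_type`, `onset_time_s`, `paired_peak_time_s`,
#'   `latency_s`, `entry_time_s`.
#' @export
pair_latencies <- function(events, tracks, onsets = NULL, overlaps = NULL,
                           max_lag_s = 120) {
  onsets <- onsets %||% detect_motility_onsets(tracks)
  overlaps <- overlaps %||% test_overlap(events, tracks)
  empty <- tibble(event_id = integer(), filo_id = integer(),
                  onset_type = character(), onset_time_s = numeric(),
                  paired_peak_time_s = numeric(), latency_s = numeric(),
                  entry_time_s = numeric())
  if (nrow(onsets) == 0) return(empty)
  ov <- overlaps[overlaps$overlap, ]
  rows <- list()
  for (i in seq_len(nrow(onsets))) {
    on <- onsets[i, ]
    ov_f <- ov[ov$filo_id == on$filo_id, ]
    if (nrow(ov_f) == 0) next
    cand <- events[events$event_id %in% ov_f$event_id, ]
    cand <- cand[cand$peak_time_s < on$onset_time_s &
                 on$onset_time_s - cand$peak_time_s <= max_lag_s, ]
    if (nrow(cand) == 0) {
      rows[[length(rows) + 1L]] <- tibble(
        event_id = NA_integer_, filo_id = on$filo_id,
        onset_type = on$onset_type, onset_time_s = on$onset_time_s,
        paired_peak_time_s = NA_real_, latency_s = NA_real_,
        entry_time_s = NA_real_)
      next
    }
    cand <- cand[order(-cand$peak_time_s, -cand$amplitude_pct), ]
    best <- cand[1, ]
    rows[[length(rows) + 1L]] <- tibble(
      event_id = best$event_id, filo_id = on$filo_id,
      onset_type = on$onset_type, onset_time_s = on$onset_time_s,
      paired_peak_time_s = best$peak_time_s,
      latency_s = on$onset_time_s - best$peak_time_s,
      entry_time_s = ov_f$entry_time_s[ov_f$event_id == best$event_id][1])
  }
  if (!length(rows)) empty else dplyr::bind_rows(rows)
}

#' Regress retraction-onset times on paired event peak times
#'
#' Ordinary least squares of `onset_time_s` on `paired_peak_time_s` over
#' the retraction records with finite latencies, reporting slope,
#' intercept and the coefficient of determination. Tight coupling at a
#' near-constant latency manifests as slope ~ 1 and R^2 near 1.
#'
#' @param records Coupling records from [pair_latencies()].
#' @return An object of class `onset_peak_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`, the underlying `lm` fit, and `insufficient = TRUE`
#'   (with `NA` coefficients) when fewer than 3 points are available.
#' @export
onset_peak_regression <- function(records) {
  pts <- records[records$onset_type == "retraction" &
                 is.finite(records$latency_s), ]
  if (nrow(pts) < 3) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n = nrow(pts), fit = NULL,
                          records = pts, insufficient = TRUE),
                     class = "onset_peak_fit"))
  }
  fit <- lm(onset_time_s ~ paired_peak_time_s, data = pts)
  # perfectly collinear inputs (R^2 = 1) are a legitimate case here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(pts), fit = fit, records = pts,
                 insufficient = FALSE),
            class = "onset_peak_fit")
}

#' @export
print.onset_peak_fit <- function(x, ...) {
  if (x$insufficient) {
    cat(sprintf("<onset_peak_fit> insufficient data (n = %d < 3)\n", x$n))
  } else {
    cat(sprintf(
      "<onset_peak_fit> onset = %.3f * peak + %.2f s, R^2 = %.4f (n = %d)\n",
      x$slope, x$intercept, x$r_squared, x$n))
  }
  invisible(x)
}

#' Bystander spatial null control
#'
#' A bystander event for a given filopodium is one whose domain never
#' contains the tip and whose centroid stays at least `inner_radius_um`
#' from the tip at every frame of the event's comparison (minimum
#' tip-to-centroid distance over the track). Latencies to bystander peaks
#' are computed exactly as in [pair_latencies()]; under the null of no
#' long-range coupling the correlation between bystander peak times and
#' onsets is centred on 0, which the bootstrap interval quantifies.
#'
#' @inheritParams pair_latencies
#' @param inner_radius_um Inner exclusion radius, um (default 7.5).
#' @param n_boot Bootstrap replicates for the correlation interval.
#' @param conf_level Bootstrap interval coverage.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return List of class `bystander_control`: `records`, `correlation`,
#'   `ci_lower`, `ci_upper`, `n`.
#' @export
bystander_control <- function(events, tracks, onsets = NULL,
                              inner_radius_um = 7.5, max_lag_s = 120,
                              n_boot = 200, conf_level = 0.95,
                              boot_seed = 1L) {
  onsets <- onsets %||% detect_motility_onsets(tracks)
  overlaps <- test_overlap(events, tracks)
  ps <- shared_pixel_size(events, tracks)
  # minimum tip-to-centroid distance per (event, filo)
  per_filo <- split(tracks, tracks$filo_id)
  bys <- list()
  for (i in seq_len(nrow(events))) {
    for (tr in per_filo) {
      dmin <- min(sqrt((tr$tip_x_um - events$x_um[i])^2 +
                       (tr$tip_y_um - events$y_um[i])^2))
      bys[[length(bys) + 1L]] <- tibble(
        event_id = events$event_id[i], filo_id = tr$filo_id[1], dmin = dmin)
    }
  }
  bys <- if (length(bys)) dplyr::bind_rows(bys) else
    tibble(event_id = integer(), filo_id = integer(), dmin = numeric())
  bys <- dplyr::left_join(bys, overlaps, by = c("event_id", "filo_id")) |>
    dplyr::filter(!.data$overlap, .data$dmin >= inner_radius_um)

  rows <- list()
  for (i in seq_len(nrow(onsets))) {
    on <- onsets[i, ]
    cand_ids <- bys$event_id[bys$filo_id == on$filo_id]
    cand <- events[events$event_id %in% cand_ids, ]
    cand <- cand[cand$peak_time_s < on$onset_time_s &
                 on$onset_time_s - cand$peak_time_s <= max_lag_s, ]
    if (nrow(cand) == 0) next
    cand <- cand[order(-cand$peak_time_s, -cand$amplitude_pct), ]
    rows[[length(rows) + 1L]] <- tibble(
      event_id = cand$event_id[1], filo_id = on$filo_id,
      onset_type = on$onset_type, onset_time_s = on$onset_time_s,
      paired_peak_time_s = cand$peak_time_s[1],
      latency_s = on$onset_time_s - cand$peak_time_s[1])
  }
  records <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(event_id = integer(), filo_id = integer(),
           onset_type = character(), onset_time_s = numeric(),
           paired_peak_time_s = numeric(), latency_s = numeric())

  correlation <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (nrow(records) >= 3 && sd(records$paired_peak_time_s) > 0 &&
      sd(records$onset_time_s) > 0) {
    correlation <- cor(records$paired_peak_time_s, records$onset_time_s)
    boots <- with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(b) {
        j <- sample(nrow(records), replace = TRUE)
        if (sd(records$paired_peak_time_s[j]) == 0 ||
            sd(records$onset_time_s[j]) == 0) return(NA_real_)
        cor(records$paired_peak_time_s[j], records$onset_time_s[j])
      }, numeric(1))
    })
    alpha <- (1 - conf_level) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(records = records, correlation = correlation,
                 ci_lower = ci[1], ci_upper = ci[2], n = nrow(records),
                 inner_radius_um = inner_radius_um),
            class = "bystander_control")
}

#' @export
print.bystander_control <- function(x, ...) {
  cat(sprintf(
    "<bystander_control> %d records beyond %.3g um: r = %.3f [%.3f, %.3f]\n",
    x$n, x$inner_radius_um, x$correlation, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Summarize event-filopodium coupling
#'
#' Collects the headline coupling statistics: the fraction of filopodial
#' tips that ever overlap an event domain, mean +/- SEM retraction latency
#' and extension interval, the onset-versus-peak regression, and (when
#' supplied) the bystander null block.
#'
#' @param records Coupling records from [pair_latencies()].
#' @param tracks A `filo_tracks` tibble.
#' @param events A `ca_events` tibble.
#' @param overlaps Overlap table; computed when missing.
#' @param bystander Optional [bystander_control()] result.
#' @return List of class `coupling_summary` with `fraction_tips_overlapping`,
#'   `n_tips`, `retraction_latency`, `extension_interval` (each mean / sem /
#'   n), `regression` (an `onset_peak_fit`), and `bystander`.
#' @export
coupling_summary <- function(records, tracks, events, overlaps = NULL,
                             bystander = NULL) {
  overlaps <- overlaps %||% test_overlap(events, tracks)
  n_tips <- length(unique(tracks$filo_id))
  frac <- if (n_tips == 0) NA_real_ else {
    length(unique(overlaps$filo_id[overlaps$overlap])) / n_tips
  }
  ret <- mean_sem(records$latency_s[records$onset_type == "retraction"])
  ext <- mean_sem(records$latency_s[records$onset_type == "extension"])
  structure(
    list(fraction_tips_overlapping = frac, n_tips = n_tips,
         retraction_latency = ret, extension_interval = ext,
         regression = onset_peak_regression(records),
         bystander = bystander),
    class = "coupling_summary")
}

#' @export
print.coupling_summary <- function(x, ...) {
  cat(sprintf("<coupling_summary> %.1f%% of %d tips overlap an event domain\n",
              100 * x$fraction_tips_overlapping, x$n_tips))
  cat(sprintf("  retraction latency %.2f +/- %.2f s (n = %d)\n",
              x$retraction_latency$mean, x$retraction_latency$sem,
              x$retraction_latency$n))
  cat(sprintf("  extension interval %.2f +/- %.2f s (n = %d)\n",
              x$extension_interval$mean, x$extension_interval$sem,
              x$extension_interval$n))
  print(x$regression)
  if (!is.null(x$bystander)) print(x$bystander)
  invisible(x)
}
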