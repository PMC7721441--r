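#' Draw the ground-truth event table for a configuration
#'
#' Samples hotspot locations and per-event parameters (peak time, amplitude,
#' FWHM, footprint radius) without rendering any pixels. [generate_ca_movie()]
#' uses this table internally; it is exported so statistical properties of
#' the generator (recurrence structure, drug-epoch rate changes) can be
#' studied cheaply at large n.
#'
#' Hotspots are placed uniformly with a margin keeping every footprint pixel
#' inside the field and a minimum mutual separation so distinct foci stay
#' resolvable. Peak times are drawn from a density that is uniform over the
#' recording, or piecewise-constant with weight `rate_multiplier` after
#' `drug_epoch$onset_s`; events at one hotspot are kept temporally separated
#' so recurrent transients do not fuse into one.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with one row per event: `event_id`, `hotspot_id`,
#'   `x_um`, `y_um`, `radius_um`, `peak_time_s`, `amplitude_pct`, `fwhm_s`,
#'   `start_s`, `end_s`.
#' @export
simulate_events <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  empty <- tibble(event_id = integer(), hotspot_id = integer(),
                  x_um = numeric(), y_um = numeric(), radius_um = numeric(),
                  peak_time_s = numeric(), amplitude_pct = numeric(),
                  fwhm_s = numeric(), start_s = numeric(), end_s = numeric())
  if (cfg$n_hotspots == 0) return(empty)
  with_seed(child_seed(cfg$seed, 1L), {
    max_r <- cfg$event_radius_um_range[2]
    margin <- max_r + 2 * cfg$pixel_size_um
    w <- cfg$field_size_um[1]; h <- cfg$field_size_um[2]
    if (w <= 2 * margin || h <= 2 * margin) {
      abort("field too small to contain event footprints at the configured radius.")
    }
    min_sep <- 2 * max_r + 2
    centers <- matrix(NA_real_, cfg$n_hotspots, 2)
    for (i in seq_len(cfg$n_hotspots)) {
      for (try in 1:500) {
        p <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
        if (i == 1 || all(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - p)^2)) >= min_sep)) {
          centers[i, ] <- p
          break
        }
      }
      if (anyNA(centers[i, ])) {
        abort("could not place hotspots with the required separation; reduce `n_hotspots` or radii.")
      }
    }

    rows <- list()
    eid <- 0L
    for (hs in seq_len(cfg$n_hotspots)) {
      n_ev <- if (cfg$events_per_hotspot_range[1] == cfg$events_per_hotspot_range[2]) {
        cfg$events_per_hotspot_range[1]
      } else {
        sample(seq(cfg$events_per_hotspot_range[1],
                   cfg$events_per_hotspot_range[2]), 1)
      }
      fwhm <- numeric(n_ev); peaks <- numeric(n_ev)
      # FWHM draws are truncated to what the recording can hold: at least
      # two frames, and short enough that the full waveform fits
      f_max <- (cfg$duration_s - 4.5) / 3
      if (f_max <= 2 * cfg$frame_interval_s) {
        abort("recording too short for the configured FWHM distribution.")
      }
      for (j in seq_len(n_ev)) {
        repeat {
          f <- rnorm(1, cfg$fwhm_s_mean, cfg$fwhm_s_sd)
          if (f >= 2 * cfg$frame_interval_s && f <= f_max) break
        }
        fwhm[j] <- f
        # waveform support: peak ~ fwhm after start, tail ~ 2*fwhm after peak
        lo <- fwhm[j] + 2; hi <- cfg$duration_s - 2 * fwhm[j] - 2
        p <- NA_real_
        for (try in 1:1000) {
          cand <- draw_peak_time(cfg, lo, hi)
          if (peaks_separated(cand, fwhm[j], peaks[seq_len(j - 1)],
                              fwhm[seq_len(j - 1)])) {
            p <- cand
            break
          }
        }
        if (is.na(p)) abort("could not separate recurrent events in time; reduce events per hotspot or lengthen the recording.")
        peaks[j] <- p
      }
      amp <- runif(n_ev, cfg$amplitude_pct_range[1], cfg$amplitude_pct_range[2])
      rad <- runif(n_ev, cfg$event_radius_um_range[1], cfg$event_radius_um_range[2])
      rows[[hs]] <- tibble(
        event_id = eid + seq_len(n_ev), hotspot_id = hs,
        x_um = centers[hs, 1], y_um = centers[hs, 2], radius_um = rad,
        peak_time_s = peaks, amplitude_pct = amp, fwhm_s = fwhm,
        start_s = pmax(0, peaks - 1.5 * fwhm),
        end_s = pmin(cfg$duration_s, peaks + 2.5 * fwhm))
      eid <- eid + n_ev
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$peak_time_s)
  })
}

# Two same-hotspot events stay distinct if the later one's rising phase
# starts after the earlier one's suprathreshold tail has decayed: for the
# asymmetric kernel the decay reach is ~1.1 FWHM past the peak and the rise
# reach ~0.6 FWHM before it, plus a safety margin.
peaks_separated <- function(p, f, peaks_prev, fwhm_prev) {
  if (!length(peaks_prev)) return(TRUE)
  ok <- ifelse(peaks_prev < p,
               p - peaks_prev >= 1.1 * fwhm_prev + 0.6 * f + 1.5,
               peaks_prev - p >= 1.1 * f + 0.6 * fwhm_prev + 1.5)
  all(ok)
}

# One peak time from the (possibly drug-weighted) time density on [lo, hi].
draw_peak_time <- function(cfg, lo, hi) {
  de <- cfg$drug_epoch
  if (is.null(de) || de$onset_s <= lo || de$onset_s >= hi) {
    return(runif(1, lo, hi))
  }
  m <- de$rate_multiplier
  w_pre <- de$onset_s - lo
  w_post <- m * (hi - de$onset_s)
  u <- runif(1, 0, w_pre + w_post)
  if (u < w_pre) lo + u else de$onset_s + (u - w_pre) / m
}

#' Render the Ca2+ indicator channel
#'
#' Renders every ground-truth event onto a constant baseline as
#' `baseline * (amplitude/100) * waveform(t) * kernel(x, y)` and then adds
#' Gaussian read noise (optionally Poisson shot noise). The spatial kernel
#' is a hard disk of the event's radius (pixels whose centre falls inside);
#' setting `edge_smooth_px > 0` tapers the rim with a Gaussian profile for
#' a softer dome. Intensities are rounded to whole 16-bit units; a signal
#' that would overflow the 16-bit range is rescaled with a warning.
#'
#' @param cfg A [sim_config()].
#' @param events Optional precomputed table from [simulate_events()];
#'   generated from `cfg` when missing.
#' @param shape Waveform family, see [generate_event_waveform()].
#' @param edge_smooth_px Gaussian rim taper width in pixels (0 = hard disk).
#' @return A list with `movie` (a [movie_stack()]) and `events` (the
#'   ground-truth tibble).
#' @examples
#' sim <- generate_ca_movie(sim_config(duration_s = 30, n_hotspots = 2,
#'                                     noise_sd = 0, seed = 7))
#' dim(sim$movie$data)
#' @export
generate_ca_movie <- function(cfg, events = NULL, shape = "alpha",
                              edge_smooth_px = 0) {
  cfg <- validate_sim_config(cfg)
  events <- events %||% simulate_events(cfg)
  nf <- n_frames_of(cfg)
  fp <- field_px_of(cfg)
  dt <- cfg$frame_interval_s
  ps <- cfg$pixel_size_um

  arr <- array(cfg$baseline_intensity, c(nf, fp["height"], fp["width"]))
  cc <- px_to_um(seq_len(fp["width"]), ps)   # pixel-centre x
  rr <- px_to_um(seq_len(fp["height"]), ps)  # pixel-centre y

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    wv <- generate_event_waveform(ev$amplitude_pct, ev$fwhm_s, dt, shape = shape)
    k_peak <- attr(wv, "peak_index")
    f_peak <- as.integer(round(ev$peak_time_s / dt)) + 1L
    f0 <- f_peak - k_peak + 1L
    frames <- seq(f0, f0 + length(wv) - 1L)
    keep <- frames >= 1 & frames <= nf
    frames <- frames[keep]; wv_k <- as.numeric(wv)[keep]

    cols <- which(abs(cc - ev$x_um) <= ev$radius_um + 3 * edge_smooth_px * ps)
    rows <- which(abs(rr - ev$y_um) <= ev$radius_um + 3 * edge_smooth_px * ps)
    d <- sqrt(outer((rr[rows] - ev$y_um)^2, (cc[cols] - ev$x_um)^2, "+"))
    kern <- if (edge_smooth_px > 0) {
      ifelse(d <= ev$radius_um, 1,
             exp(-((d - ev$radius_um) / (edge_smooth_px * ps))^2 / 2))
    } else {
      as.numeric(d <= ev$radius_um)
    }
    if (!any(kern > 0)) next
    gain <- cfg$baseline_intensity * ev$amplitude_pct / 100
    for (k in seq_along(frames)) {
      arr[frames[k], rows, cols] <- arr[frames[k], rows, cols] +
        gain * (wv_k[k] / ev$amplitude_pct) * kern
    }
  }

  arr <- with_seed(child_seed(cfg$seed, 2L), {
    if (cfg$noise_sd > 0) arr <- arr + rnorm(length(arr), 0, cfg$noise_sd)
    if (cfg$poisson_noise) arr <- stats::rpois(length(arr), pmax(arr, 0))
    arr
  })
  arr <- round(pmax(arr, 0))
  if (max(arr) > 65535) {
    warn("rendered intensities exceed the 16-bit range; rescaling to fit.")
    arr <- round(arr * (65535 / max(arr)))
  }
  dim(arr) <- c(nf, fp[["height"]], fp[["width"]])
  list(movie = movie_stack(arr, dt, ps, channel = "ca"), events = events)
}
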