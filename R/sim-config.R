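#' Simulation configuration
#'
#' Builds and validates the configuration object for the synthetic
#' two-channel movie generator. Defaults reproduce the acquisition and
#' biology this package targets: 6-minute single-plane recordings at 300 ms
#' per frame, microdomain transients recurring at fixed hotspots (1-3 events
#' per focus) with FWHM drawn from a 5.5 +/- 2.26 s distribution, tracheal
#' filopodia in four motility categories, and an optional coupling rule in
#' which an overlapping filopodium begins retracting 25.9 s (plus Gaussian
#' jitter) after a Ca2+ event peak.
#'
#' @param duration_s Recording duration in seconds.
#' @param frame_interval_s Frame interval in seconds; `duration_s /
#'   frame_interval_s` must be a whole number of frames.
#' @param field_size_um Length-2 numeric, field width and height in um.
#' @param pixel_size_um Pixel size in um/pixel (default 1/3: a 100 um
#'   window spanning 300 px).
#' @param baseline_intensity Constant baseline fluorescence, arbitrary
#'   16-bit units.
#' @param noise_sd SD of additive Gaussian noise (intensity units).
#' @param poisson_noise If `TRUE`, replace each noisy intensity with a
#'   Poisson draw at that mean (shot noise); off by default.
#' @param n_hotspots Number of recurrence foci for spontaneous events.
#' @param events_per_hotspot_range Integer `(min, max)` events per focus.
#' @param amplitude_pct_range `(min, max)` event amplitude, percent dF/F0.
#' @param fwhm_s_mean,fwhm_s_sd Mean and SD (seconds) of the event FWHM
#'   distribution (normal, truncated at twice the frame interval).
#' @param event_radius_um_range `(min, max)` event footprint radius, um.
#' @param n_filopodia Number of tracheal filopodia.
#' @param category_proportions Length-4 numeric summing to 1: fractions of
#'   filopodia in the extension, retraction, extension-and-retraction and
#'   stationary categories (defaults 0.017, 0.207, 0.753, 0.023).
#' @param extension_rate_um_per_min,retraction_rate_um_per_min Tip speeds.
#' @param coupling_enabled If `TRUE`, extension-and-retraction filopodia are
#'   steered into an event footprint and begin retracting at the event peak
#'   plus `coupling_latency_s` plus jitter.
#' @param coupling_latency_s Peak-to-retraction-onset latency, seconds.
#' @param coupling_jitter_sd_s SD of the Gaussian latency jitter, seconds.
#' @param drug_epoch Optional list `(onset_s, rate_multiplier)`: after
#'   `onset_s` the event rate density is multiplied by `rate_multiplier`,
#'   emulating bath application of a drug halfway through the recording.
#' @param seed Integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_hotspots = 4, n_filopodia = 3, seed = 1)
#' cfg$duration_s / cfg$frame_interval_s
#' @export
sim_config <- function(duration_s = 360,
                       frame_interval_s = 0.3,
                       field_size_um = c(100 / 3, 100 / 3),
                       pixel_size_um = 1 / 3,
                       baseline_intensity = 1000,
                       noise_sd = 10,
                       poisson_noise = FALSE,
                       n_hotspots = 8,
                       events_per_hotspot_range = c(1L, 3L),
                       amplitude_pct_range = c(10, 30),
                       fwhm_s_mean = 5.5,
                       fwhm_s_sd = 2.26,
                       event_radius_um_range = c(1.5, 3),
                       n_filopodia = 6,
                       category_proportions = c(0.017, 0.207, 0.753, 0.023),
                       extension_rate_um_per_min = 2,
                       retraction_rate_um_per_min = 3,
                       coupling_enabled = FALSE,
                       coupling_latency_s = 25.9,
                       coupling_jitter_sd_s = 2.18,
                       drug_epoch = NULL,
                       seed = 1L) {
  cfg <- list(
    duration_s = duration_s, frame_interval_s = frame_interval_s,
    field_size_um = as.numeric(field_size_um),
    pixel_size_um = pixel_size_um,
    baseline_intensity = baseline_intensity, noise_sd = noise_sd,
    poisson_noise = isTRUE(poisson_noise),
    n_hotspots = as.integer(n_hotspots),
    events_per_hotspot_range = as.integer(events_per_hotspot_range),
    amplitude_pct_range = as.numeric(amplitude_pct_range),
    fwhm_s_mean = fwhm_s_mean, fwhm_s_sd = fwhm_s_sd,
    event_radius_um_range = as.numeric(event_radius_um_range),
    n_filopodia = as.integer(n_filopodia),
    category_proportions = as.numeric(category_proportions),
    extension_rate_um_per_min = extension_rate_um_per_min,
    retraction_rate_um_per_min = retraction_rate_um_per_min,
    coupling_enabled = isTRUE(coupling_enabled),
    coupling_latency_s = coupling_latency_s,
    coupling_jitter_sd_s = coupling_jitter_sd_s,
    drug_epoch = drug_epoch, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` to validate.
#' @export
validate_sim_config <- function(cfg) {
  n_frames <- cfg$duration_s / cfg$frame_interval_s
  if (cfg$duration_s <= 0 || cfg$frame_interval_s <= 0 ||
      abs(n_frames - round(n_frames)) > 1e-9 || round(n_frames) < 1) {
    abort("`duration_s / frame_interval_s` must be a positive whole number of frames.")
  }
  if (length(cfg$field_size_um) != 2 || any(cfg$field_size_um <= 0)) {
    abort("`field_size_um` must be two positive numbers (width, height).")
  }
  if (abs(sum(cfg$category_proportions) - 1) > 1e-9 ||
      length(cfg$category_proportions) != 4 ||
      any(cfg$category_proportions < 0)) {
    abort("`category_proportions` must be 4 non-negative fractions summing to 1.")
  }
  ranges <- list(events_per_hotspot_range = cfg$events_per_hotspot_range,
                 amplitude_pct_range = cfg$amplitude_pct_range,
                 event_radius_um_range = cfg$event_radius_um_range)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2] || any(r < 0)) {
      abort(sprintf("`%s` must satisfy 0 <= min <= max.", nm))
    }
  }
  nonneg <- c(noise_sd = cfg$noise_sd, fwhm_s_sd = cfg$fwhm_s_sd,
              extension_rate_um_per_min = cfg$extension_rate_um_per_min,
              retraction_rate_um_per_min = cfg$retraction_rate_um_per_min,
              coupling_jitter_sd_s = cfg$coupling_jitter_sd_s,
              n_hotspots = cfg$n_hotspots, n_filopodia = cfg$n_filopodia)
  if (any(nonneg < 0)) {
    abort(sprintf("negative value for %s.",
                  paste(names(nonneg)[nonneg < 0], collapse = ", ")))
  }
  if (!is.null(cfg$drug_epoch)) {
    de <- cfg$drug_epoch
    if (!all(c("onset_s", "rate_multiplier") %in% names(de)) ||
        de$onset_s <= 0 || de$onset_s >= cfg$duration_s ||
        de$rate_multiplier < 0) {
      abort("`drug_epoch` needs onset_s inside the recording and rate_multiplier >= 0.")
    }
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %gs at %gs/frame (%d frames), %g x %g um field ",
           "(%g um/px)\n  %d hotspots, %d filopodia, coupling %s, seed %d\n"),
    x$duration_s, x$frame_interval_s, x$duration_s / x$frame_interval_s,
    x$field_size_um[1], x$field_size_um[2], x$pixel_size_um,
    x$n_hotspots, x$n_filopodia,
    if (x$coupling_enabled) "on" else "off", x$seed))
  invisible(x)
}

n_frames_of <- function(cfg) as.integer(round(cfg$duration_s / cfg$frame_interval_s))

field_px_of <- function(cfg) {
  c(height = as.integer(round(cfg$field_size_um[2] / cfg$pixel_size_um)),
    width = as.integer(round(cfg$field_size_um[1] / cfg$pixel_size_um)))
}

#' Read / write a simulation configuration file
#'
#' Configurations are stored as a single YAML document whose keys mirror the
#' arguments of [sim_config()]; unknown keys are rejected so typos fail
#' loudly.
#'
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(bad, collapse = ", ")))
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param cfg A [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
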