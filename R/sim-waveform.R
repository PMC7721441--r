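#' Generate a sampled Ca2+ transient waveform
#'
#' Returns a dF/F0 time course (in percent) sampled at the frame interval,
#' normalized so the largest sample equals `amplitude_pct` and the width at
#' half maximum, measured by linear interpolation between samples, lies
#' within one frame interval of `fwhm_s`. The trace starts and ends at 0.
#'
#' The default `"alpha"` family is an asymmetric rise/decay kernel (fast
#' half-Gaussian rise, twice-slower half-Gaussian decay), a generic shape
#' for near-membrane microdomain transients whose exact waveform varies
#' from event to event. Symmetric `"triangle"` and `"gaussian"` kernels are
#' provided as analytically tractable test shapes.
#'
#' @param amplitude_pct Peak amplitude in percent dF/F0 (> 0).
#' @param fwhm_s Target full width at half maximum, seconds; must be at
#'   least twice the frame interval or the waveform cannot be resolved.
#' @param frame_interval_s Sampling interval, seconds.
#' @param shape One of `"alpha"`, `"triangle"`, `"gaussian"`.
#' @return Numeric vector of dF/F0 samples in percent, starting at relative
#'   time 0, with attributes `peak_index` and `times_s`.
#' @examples
#' w <- generate_event_waveform(10, 5.5, 0.3)
#' max(w)
#' @export
generate_event_waveform <- function(amplitude_pct, fwhm_s, frame_interval_s,
                                    shape = c("alpha", "triangle", "gaussian")) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude_pct) || amplitude_pct <= 0) {
    abort("`amplitude_pct` must be > 0.")
  }
  if (fwhm_s < 2 * frame_interval_s) {
    abort(sprintf(
      "FWHM of %.3g s is below the temporal resolution: need at least two frames (%.3g s).",
      fwhm_s, 2 * frame_interval_s))
  }
  hwc <- sqrt(2 * log(2))  # half-width at half max of a unit Gaussian, in sigmas
  f <- switch(shape,
    triangle = {
      # symmetric triangle: rise over fwhm_s, fall over fwhm_s
      peak_t <- fwhm_s
      total <- 2 * fwhm_s
      function(t) pmax(0, 1 - abs(t - peak_t) / fwhm_s)
    },
    gaussian = {
      sigma <- fwhm_s / (2 * hwc)
      peak_t <- 3.5 * sigma
      total <- 7 * sigma
      function(t) exp(-(t - peak_t)^2 / (2 * sigma^2))
    },
    alpha = {
      # asymmetric: half-Gaussian rise (sigma_r), half-Gaussian decay
      # (sigma_d = 2 sigma_r); FWHM = (sigma_r + sigma_d) * hwc
      sigma_r <- fwhm_s / (3 * hwc)
      sigma_d <- 2 * sigma_r
      peak_t <- 3.5 * sigma_r
      total <- 3.5 * sigma_r + 3.5 * sigma_d
      function(t) ifelse(t <= peak_t,
                         exp(-(t - peak_t)^2 / (2 * sigma_r^2)),
                         exp(-(t - peak_t)^2 / (2 * sigma_d^2)))
    })
  t <- seq(0, total, by = frame_interval_s)
  y <- f(t)
  # pin the support ends to exactly zero (tails are < 0.3% of peak here)
  y <- pmax(0, y - max(y[1], y[length(y)]))
  y <- y / max(y) * amplitude_pct
  structure(y, peak_index = which.max(y), times_s = t)
}

#' Interpolated full width at half maximum of a sampled trace
#'
#' Measures the time between the two half-maximum crossings nearest the
#' peak, found by linear interpolation between samples. Used both by the
#' event measurement stage and to verify generated waveforms.
#'
#' @param y Numeric trace (any units; baseline assumed near 0).
#' @param dt Sampling interval, seconds.
#' @param peak_index Optional index of the peak; defaults to `which.max(y)`.
#' @return A list with `fwhm_s`, `left_s`, `right_s`, and logical
#'   `left_censored` / `right_censored` flags set when the trace never falls
#'   below half maximum inside the record on that side (in which case
#'   `fwhm_s` is `NA`).
#' @export
trace_fwhm <- function(y, dt, peak_index = NULL) {
  peak_index <- peak_index %||% which.max(y)
  half <- y[peak_index] / 2
  t <- (seq_along(y) - 1) * dt

  cross_left <- NA_real_
  for (i in (if (peak_index >= 2) peak_index:2 else integer(0))) {
    if (y[i - 1] < half && y[i] >= half) {
      frac <- (half - y[i - 1]) / (y[i] - y[i - 1])
      cross_left <- t[i - 1] + frac * dt
      break
    }
  }
  cross_right <- NA_real_
  if (peak_index < length(y)) {
    for (i in seq(peak_index, length(y) - 1L)) {
      if (y[i] >= half && y[i + 1] < half) {
        frac <- (y[i] - half) / (y[i] - y[i + 1])
        cross_right <- t[i] + frac * dt
        break
      }
    }
  }
  list(fwhm_s = if (is.na(cross_left) || is.na(cross_right)) NA_real_
               else cross_right - cross_left,
       left_s = cross_left, right_s = cross_right,
       left_censored = is.na(cross_left),
       right_censored = is.na(cross_right))
}
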