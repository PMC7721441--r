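# One rectangular test transient: a 3x3 px block raised by `delta` units
# over `frames`, on a flat baseline of 1000.
block_movie <- function(delta, frames = 5:7, n_frames = 20, size = 12,
                        at = c(5, 5)) {
  arr <- array(1000, c(n_frames, size, size))
  arr[frames, at[1]:(at[1] + 2), at[2]:(at[2] + 2)] <-
    1000 + delta
  movie_stack(arr, 0.3, 1/3)
}

test_that("nothing is detected in a flat dF/F0 movie", {
  ev <- detect_events(compute_dff(block_movie(0)))
  expect_equal(nrow(ev), 0)
})

test_that("the detection cutoff is inclusive at exactly 5% dF/F0", {
  ev <- detect_events(compute_dff(block_movie(50)))   # 50/1000 = 5.0%
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_pct, 5)
  ev_below <- detect_events(compute_dff(block_movie(49)))  # 4.9%
  expect_equal(nrow(ev_below), 0)
})

test_that("disjoint noise-free transients match the brute-force flood fill exactly", {
  cfg <- sim_config(duration_s = 60, field_size_um = c(24, 24),
                    n_hotspots = 5, events_per_hotspot_range = c(1, 1),
                    amplitude_pct_range = c(10, 20),
                    event_radius_um_range = c(1, 2), n_filopodia = 0,
                    noise_sd = 0, seed = 17)
  sim <- generate_ca_movie(cfg)
  dff <- compute_dff(sim$movie)
  ev <- detect_events(dff, close_time_gaps = 0)
  expect_equal(nrow(ev), 5)

  mask <- !is.na(dff$dff) & dff$dff >= 0.05 - 1e-12
  comps <- oracle_flood_fill(mask)
  comps <- Filter(function(m) length(unique(m[, 1])) >= 2 &&
                    nrow(unique(m[, 2:3, drop = FALSE])) >= 4, comps)
  expect_equal(length(comps), nrow(ev))
  # footprints (unions over lifetime) must agree pixel for pixel
  canon <- function(m) {
    m <- unique(m[, , drop = FALSE])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  det_fps <- lapply(ev$footprint, canon)
  ora_fps <- lapply(comps, function(m) canon(m[, 2:3, drop = FALSE]))
  key <- function(m) paste(m[, 1], m[, 2], sep = ",", collapse = ";")
  expect_setequal(vapply(det_fps, key, ""), vapply(ora_fps, key, ""))
})

test_that("lowering the cutoff never decreases the event count", {
  # disjoint footprints: thresholding alone decides, so counts are monotone
  cfg <- sim_config(duration_s = 60, field_size_um = c(24, 24),
                    n_hotspots = 5, amplitude_pct_range = c(6, 20),
                    event_radius_um_range = c(1, 2),
                    n_filopodia = 0, noise_sd = 0, seed = 18)
  dff <- compute_dff(generate_ca_movie(cfg)$movie)
  counts <- vapply(c(12, 9, 7, 5, 4), function(cut)
    nrow(detect_events(dff, cutoff_pct = cut)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("injected events are recovered accurately under realistic noise", {
  cfg <- sim_config(duration_s = 120, field_size_um = c(30, 30),
                    n_hotspots = 8, events_per_hotspot_range = c(1, 1),
                    amplitude_pct_range = c(10, 25), n_filopodia = 0,
                    noise_sd = 10, seed = 19)
  sim <- generate_ca_movie(cfg)
  ev <- detect_events(compute_dff(sim$movie))
  expect_equal(nrow(ev), nrow(sim$events))    # no misses, no spurious events
  matched <- 0
  for (i in seq_len(nrow(sim$events))) {
    gt <- sim$events[i, ]
    d <- sqrt((ev$x_um - gt$x_um)^2 + (ev$y_um - gt$y_um)^2)
    j <- which.min(d + abs(ev$peak_time_s - gt$peak_time_s))
    if (d[j] <= 2 * (1 / 3)) matched <- matched + 1   # centroid within 2 px
  }
  expect_gte(matched / nrow(sim$events), 0.95)
})

test_that("amplitude is exact on noise-free input and FWHM tracks the waveform", {
  cfg <- sim_config(duration_s = 90, field_size_um = c(25, 25),
                    n_hotspots = 4, events_per_hotspot_range = c(1, 1),
                    amplitude_pct_range = c(12, 24), n_filopodia = 0,
                    noise_sd = 0, seed = 20)
  sim <- generate_ca_movie(cfg)
  ev <- detect_events(compute_dff(sim$movie))
  expect_equal(nrow(ev), 4)
  ord <- order(ev$peak_time_s); gt <- sim$events[order(sim$events$peak_time_s), ]
  # one quantization step is 1 intensity unit = 0.1% of the 1000 baseline
  expect_true(all(abs(ev$amplitude_pct[ord] - gt$amplitude_pct) <= 0.11))
  expect_true(all(abs(ev$fwhm_s[ord] - gt$fwhm_s) <= 2 * 0.3))
})

test_that("the aligned trace has its peak at sample index 20 of 0..40", {
  ev <- detect_events(compute_dff(block_movie(120, frames = 30:34,
                                              n_frames = 60)))
  expect_equal(nrow(ev), 1)
  tr <- ev$aligned_trace[[1]]
  expect_length(tr, 41)
  expect_equal(which.max(tr) - 1, 20)   # 0-based index 20
  expect_false(ev$edge_flagged)
})

test_that("events near the movie edge are boundary-padded and flagged", {
  ev <- detect_events(compute_dff(block_movie(120, frames = 3:5,
                                              n_frames = 20)))
  expect_equal(nrow(ev), 1)
  expect_true(ev$edge_flagged)
  expect_length(ev$aligned_trace[[1]], 41)
})

test_that("a plateau that never falls below half maximum is censored, not numeric", {
  arr <- array(100, c(20, 6, 6))
  arr[, 3:4, 3:4] <- 112                 # 12% above the global baseline forever
  d <- compute_dff(movie_stack(arr, 0.3, 1/3), baseline_method = "global",
                   f0 = 100)
  ev <- detect_events(d)
  expect_equal(nrow(ev), 1)
  expect_true(ev$fwhm_censored)
  expect_true(is.na(ev$fwhm_s))
})
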