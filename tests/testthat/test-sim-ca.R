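test_that("frame count follows the configured duration and interval", {
  cfg <- sim_config(duration_s = 360, frame_interval_s = 0.3,
                    field_size_um = c(8, 8), n_hotspots = 0, seed = 1)
  sim <- generate_ca_movie(cfg)
  expect_equal(dim(sim$movie$data)[1], 1200)
  expect_error(sim_config(duration_s = 10, frame_interval_s = 0.3),
               "whole number")
})

test_that("a hotspot-free noise-free movie yields zero detected events", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(15, 15),
                    n_hotspots = 0, n_filopodia = 0, noise_sd = 0, seed = 2)
  sim <- generate_ca_movie(cfg)
  expect_true(all(sim$movie$data == cfg$baseline_intensity))
  ev <- detect_events(compute_dff(sim$movie))
  expect_equal(nrow(ev), 0)
})

test_that("rendered events match the brute-force suprathreshold component count", {
  cfg <- sim_config(duration_s = 120, field_size_um = c(40, 40),
                    n_hotspots = 12, events_per_hotspot_range = c(1, 1),
                    amplitude_pct_range = c(10, 10), n_filopodia = 0,
                    noise_sd = 0, seed = 3)
  sim <- generate_ca_movie(cfg)
  expect_equal(nrow(sim$events), 12)
  dff <- compute_dff(sim$movie)
  mask <- !is.na(dff$dff) & dff$dff >= 0.05 - 1e-12
  comps <- oracle_flood_fill(mask)
  big <- Filter(function(m) length(unique(m[, 1])) >= 2 &&
                  nrow(unique(m[, 2:3, drop = FALSE])) >= 4, comps)
  expect_equal(length(big), 12)
})

test_that("generation is a pure function of the configuration", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(20, 20),
                    n_hotspots = 3, event_radius_um_range = c(1, 2),
                    events_per_hotspot_range = c(1, 1), n_filopodia = 0,
                    seed = 7)
  a <- generate_ca_movie(cfg)
  b <- generate_ca_movie(cfg)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$events, b$events)
})

test_that("event footprints stay inside the field across seeds", {
  for (seed in 1:5) {
    cfg <- sim_config(duration_s = 120, field_size_um = c(30, 30),
                      n_hotspots = 5, n_filopodia = 0, seed = seed)
    ev <- simulate_events(cfg)
    expect_true(all(ev$x_um - ev$radius_um >= 0))
    expect_true(all(ev$x_um + ev$radius_um <= 30))
    expect_true(all(ev$y_um - ev$radius_um >= 0))
    expect_true(all(ev$y_um + ev$radius_um <= 30))
  }
})

test_that("a drug epoch reweights event peak times by the rate multiplier", {
  cfg <- sim_config(duration_s = 360, field_size_um = c(200, 200),
                    n_hotspots = 300, events_per_hotspot_range = c(1, 1),
                    n_filopodia = 0,
                    drug_epoch = list(onset_s = 180, rate_multiplier = 3),
                    seed = 9)
  ev <- simulate_events(cfg)
  frac_post <- mean(ev$peak_time_s >= 180)
  # feasible windows are near-symmetric around 180 s, so expected post
  # fraction is ~ 3 / (1 + 3) = 0.75
  expect_gt(frac_post, 0.65)
  expect_lt(frac_post, 0.85)
})

test_that("intensities that would overflow 16 bits are rescaled with a warning", {
  cfg <- sim_config(duration_s = 39, field_size_um = c(20, 20),
                    n_hotspots = 2, events_per_hotspot_range = c(1, 1),
                    event_radius_um_range = c(1, 2),
                    amplitude_pct_range = c(30, 30),
                    baseline_intensity = 60000, n_filopodia = 0, seed = 4)
  expect_warning(sim <- generate_ca_movie(cfg), "16-bit")
  expect_lte(max(sim$movie$data), 65535)
})
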