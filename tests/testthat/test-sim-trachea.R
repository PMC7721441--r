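test_that("a stationary filopodium has a constant true length trace", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(20, 20),
                    n_hotspots = 0, n_filopodia = 1, noise_sd = 0,
                    category_proportions = c(0, 0, 0, 1), seed = 5)
  gt <- simulate_filopodia(cfg)
  expect_equal(gt$filopodia$category, "stationary")
  expect_equal(length(unique(gt$frames$length_um)), 1)
})

test_that("a coupled filopodium retracts at peak + latency + jitter", {
  cfg <- sim_config(duration_s = 240, field_size_um = c(45, 45),
                    n_hotspots = 6, n_filopodia = 3, noise_sd = 0,
                    category_proportions = c(0, 0, 1, 0),
                    coupling_enabled = TRUE, coupling_latency_s = 26,
                    coupling_jitter_sd_s = 0, seed = 6)
  ev <- simulate_events(cfg)
  gt <- simulate_filopodia(cfg, ev)
  coupled <- gt$filopodia[gt$filopodia$coupled, ]
  expect_gt(nrow(coupled), 0)
  peaks <- ev$peak_time_s[match(coupled$coupled_event_id, ev$event_id)]
  expect_equal(coupled$retraction_onset_s, peaks + 26, tolerance = 1e-9)
})

test_that("category assignment reproduces an independent seeded draw", {
  props <- c(0.017, 0.207, 0.753, 0.023)
  cfg <- sim_config(duration_s = 30, field_size_um = c(220, 220),
                    n_hotspots = 0, n_filopodia = 100, noise_sd = 0,
                    category_proportions = props, seed = 31)
  gt <- simulate_filopodia(cfg)
  cats <- c("extension", "retraction", "extension_and_retraction", "stationary")
  redraw <- filocal:::with_seed(filocal:::child_seed(31, 3L),
                                sample(cats, 100, replace = TRUE, prob = props))
  expect_identical(gt$filopodia$category, redraw)
  expect_equal(sum(table(factor(gt$filopodia$category, cats))), 100)
})

test_that("true tip positions stay inside the field", {
  for (seed in 1:4) {
    cfg <- sim_config(duration_s = 120, field_size_um = c(40, 40),
                      n_hotspots = 4, n_filopodia = 5,
                      category_proportions = c(0.25, 0.25, 0.25, 0.25),
                      coupling_enabled = TRUE, seed = seed)
    gt <- simulate_filopodia(cfg, simulate_events(cfg))
    expect_true(all(gt$frames$tip_x_um >= 0 & gt$frames$tip_x_um <= 40))
    expect_true(all(gt$frames$tip_y_um >= 0 & gt$frames$tip_y_um <= 40))
    expect_true(all(gt$frames$length_um >= 0))
  }
})

test_that("injected onset-peak differences recover the latency and jitter settings", {
  diffs <- c()
  for (seed in 1:35) {
    cfg <- sim_config(duration_s = 360, field_size_um = c(70, 70),
                      n_hotspots = 12, events_per_hotspot_range = c(1, 1),
                      n_filopodia = 8, noise_sd = 0,
                      category_proportions = c(0, 0, 1, 0),
                      coupling_enabled = TRUE, seed = seed)
    ev <- simulate_events(cfg)
    gt <- simulate_filopodia(cfg, ev)
    cp <- gt$filopodia[gt$filopodia$coupled, ]
    diffs <- c(diffs, cp$retraction_onset_s -
                 ev$peak_time_s[match(cp$coupled_event_id, ev$event_id)])
  }
  expect_gte(length(diffs), 200)
  expect_lt(abs(mean(diffs) - 25.9) / 25.9, 0.15)
  expect_lt(abs(sd(diffs) - 2.18) / 2.18, 0.15)
})
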