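test_that("a static filopodium yields one track with a constant length trace", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(20, 20),
                    n_hotspots = 0, n_filopodia = 1, noise_sd = 0,
                    category_proportions = c(0, 0, 0, 1), seed = 51)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie)
  expect_equal(length(unique(tk$filo_id)), 1)
  expect_lt(diff(range(tk$length_um)), 1e-9)
  expect_equal(nrow(tk), 100)
})

test_that("a steadily extending filopodium is recovered within one pixel at every frame", {
  cfg <- sim_config(duration_s = 120, field_size_um = c(30, 30),
                    n_hotspots = 0, n_filopodia = 1, noise_sd = 0,
                    category_proportions = c(1, 0, 0, 0), seed = 52)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie)
  expect_equal(length(unique(tk$filo_id)), 1)
  gt <- tr$frames
  m <- merge(as.data.frame(tk), as.data.frame(gt), by = "frame")
  expect_true(all(abs(m$length_um.x - m$length_um.y) <= 1 / 3))
  expect_true(all(sqrt((m$tip_x_um.x - m$tip_x_um.y)^2 +
                       (m$tip_y_um.x - m$tip_y_um.y)^2) <= 1 / 3))
})

test_that("two separated filopodia keep their identities at every frame", {
  cfg <- sim_config(duration_s = 60, field_size_um = c(35, 35),
                    n_hotspots = 0, n_filopodia = 2, noise_sd = 5,
                    category_proportions = c(0.5, 0.5, 0, 0), seed = 53)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie)
  expect_equal(length(unique(tk$filo_id)), 2)
  bases <- track_bases(tk)
  # match each recovered track to the nearest true base, require a bijection
  assign <- vapply(seq_len(2), function(i) {
    which.min((tr$filopodia$base_x_um - bases$base_x_um[i])^2 +
              (tr$filopodia$base_y_um - bases$base_y_um[i])^2)
  }, integer(1))
  expect_setequal(assign, 1:2)
  for (i in 1:2) {
    gt <- tr$frames[tr$frames$filo_id == assign[i], ]
    got <- tk[tk$filo_id == i, ]
    m <- merge(as.data.frame(got), as.data.frame(gt), by = "frame")
    expect_true(all(sqrt((m$tip_x_um.x - m$tip_x_um.y)^2 +
                         (m$tip_y_um.x - m$tip_y_um.y)^2) < 1.5))
  }
})

test_that("precomputed tip tables bypass imaging and reproduce lengths", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(25, 25),
                    n_hotspots = 0, n_filopodia = 2, noise_sd = 0,
                    category_proportions = c(0.5, 0, 0.5, 0), seed = 54)
  gt <- simulate_filopodia(cfg)
  tips <- data.frame(filo_id = gt$frames$filo_id, frame = gt$frames$frame,
                     time_s = gt$frames$time_s,
                     x_um = gt$frames$tip_x_um, y_um = gt$frames$tip_y_um,
                     base_x_um = gt$filopodia$base_x_um[gt$frames$filo_id],
                     base_y_um = gt$filopodia$base_y_um[gt$frames$filo_id])
  tk <- track_tips(tips = tips)
  expect_equal(tk$length_um, gt$frames$length_um, tolerance = 1e-9)
  # without base columns, lengths are relative to the first tip position
  tk2 <- track_tips(tips = tips[, 1:5])
  first_len <- tk2$length_um[tk2$frame == 1]
  expect_equal(first_len, c(0, 0))
})

test_that("short-lived detections are dropped by the lifetime filter", {
  cfg <- sim_config(duration_s = 30, field_size_um = c(20, 20),
                    n_hotspots = 0, n_filopodia = 1, noise_sd = 0,
                    category_proportions = c(0, 0, 0, 1), seed = 55)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie, min_lifetime_frames = 5000)
  expect_equal(nrow(tk), 0)
})
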