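# Wrap a bare length trace as a minimal filo_tracks tibble.
as_track <- function(len, dt = 1, id = 1L) {
  tibble::tibble(filo_id = id, frame = seq_along(len),
                 time_s = (seq_along(len) - 1) * dt,
                 tip_x_um = 0, tip_y_um = 0, length_um = len,
                 interpolated = FALSE)
}

test_that("a trace that declines from frame k scores one retraction onset at k", {
  len <- c(rep(10, 19), 10 - 0.2 * (1:30))   # decline starts after frame 19
  on <- detect_motility_onsets(as_track(len))
  expect_equal(nrow(on), 1)
  expect_equal(on$onset_type, "retraction")
  expect_equal(on$onset_frame, 19)
  # a trace already declining at its first frame anchors the onset there
  on2 <- detect_motility_onsets(as_track(10 - 0.2 * (0:30)))
  expect_equal(on2$onset_frame, 1)
})

test_that("constant traces yield no onsets and classify as stationary", {
  on <- detect_motility_onsets(as_track(rep(4, 50)))
  expect_equal(nrow(on), 0)
  cl <- classify_tracks(as_track(rep(4, 50)))
  expect_equal(cl$category, "stationary")
})

test_that("onsets in noisy plateau-then-ramp traces land within one frame of truth", {
  for (seed in 1:8) {
    set.seed(seed)
    k <- sample(20:40, 1)
    len <- c(rep(8, k), 8 - 0.15 * (1:40)) + rnorm(k + 40, 0, 0.04)
    on <- detect_motility_onsets(as_track(len), min_change_um = 0.5,
                                 min_frames = 3)
    ret <- on[on$onset_type == "retraction", ]
    expect_equal(nrow(ret), 1)
    expect_lte(abs(ret$onset_frame - k), 1)
  }
})

test_that("sub-threshold plateaus split a decline into distinct onsets", {
  len <- c(rep(10, 5), 10 - 0.3 * (1:10), rep(7, 15), 7 - 0.3 * (1:10))
  on <- detect_motility_onsets(as_track(len), min_change_um = 0.5,
                               min_frames = 3)
  expect_equal(sum(on$onset_type == "retraction"), 2)
})

test_that("rise-then-fall classifies as extension_and_retraction with correct rates", {
  len <- c(seq(4, 8, by = 0.1), seq(8, 5, by = -0.15)[-1])
  tk <- as_track(len, dt = 2)   # 0.1 um / 2 s up, 0.15 um / 2 s down
  cl <- classify_tracks(tk)
  expect_equal(cl$category, "extension_and_retraction")
  expect_equal(cl$mean_extension_rate_um_per_min, 3, tolerance = 0.05)
  expect_equal(cl$mean_retraction_rate_um_per_min, 4.5, tolerance = 0.05)
})

test_that("a track extending 1 um per 30 s has a 2 um/min extension rate and no retraction", {
  len <- 4 + (0:99) * (1 / 30)   # dt = 1 s
  mm <- motility_metrics(as_track(len))
  r <- mm$rates
  expect_equal(r$mean[r$metric == "extension_rate_um_per_min"], 2,
               tolerance = 0.01)
  expect_equal(r$n[r$metric == "retraction_rate_um_per_min"], 0)
})

test_that("noise-free generated cohorts are classified in full agreement with ground truth", {
  cfg <- sim_config(duration_s = 240, field_size_um = c(50, 50),
                    n_hotspots = 0, n_filopodia = 8, noise_sd = 0,
                    category_proportions = c(0.25, 0.25, 0.25, 0.25),
                    seed = 61)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie)
  cl <- classify_tracks(tk)
  bases <- track_bases(tk)
  expect_equal(nrow(cl), 8)
  assign <- vapply(seq_len(nrow(bases)), function(i) {
    which.min((tr$filopodia$base_x_um - bases$base_x_um[i])^2 +
              (tr$filopodia$base_y_um - bases$base_y_um[i])^2)
  }, integer(1))
  expect_setequal(assign, 1:8)
  expect_identical(cl$category, tr$filopodia$category[assign])
})

test_that("generated motility rates are recovered within 5% on noise-free input", {
  cfg <- sim_config(duration_s = 180, field_size_um = c(60, 60),
                    n_hotspots = 0, n_filopodia = 6, noise_sd = 0,
                    extension_rate_um_per_min = 2,
                    retraction_rate_um_per_min = 3,
                    category_proportions = c(0, 0, 1, 0), seed = 62)
  tr <- generate_trachea_movie(cfg)
  tk <- track_tips(tr$movie)
  mm <- motility_metrics(tk)
  r <- mm$rates
  expect_lt(abs(r$mean[r$metric == "extension_rate_um_per_min"] - 2) / 2, 0.05)
  expect_lt(abs(r$mean[r$metric == "retraction_rate_um_per_min"] - 3) / 3, 0.05)
})

test_that("raising the hysteresis threshold never increases the onset count", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    len <- 6 + cumsum(rnorm(300, 0, 0.12))
    len <- pmax(len, 0.5)
    counts <- vapply(c(0.3, 0.5, 0.8, 1.2, 2), function(mc)
      nrow(detect_motility_onsets(as_track(len), min_change_um = mc)),
      numeric(1))
    expect_true(all(diff(counts) <= 0),
                label = sprintf("monotone onset counts (seed %d)", seed))
  }
})

test_that("classification is invariant to padding with constant frames", {
  len <- c(seq(5, 8, by = 0.1), seq(8, 6, by = -0.1)[-1])
  base <- classify_tracks(as_track(len))$category
  padded <- classify_tracks(as_track(c(rep(5, 20), len, rep(tail(len, 1), 20))))$category
  expect_identical(base, padded)
  expect_identical(classify_tracks(as_track(len))$category, base)  # deterministic
})

test_that("an epoch without retraction onsets reports an undefined ratio", {
  len <- c(seq(4, 9, by = 0.05), seq(9, 5, by = -0.05)[-1])
  tk <- as_track(len, dt = 1)
  mm <- motility_metrics(tk, epoch_split_s = 50)
  expect_true(mm$epochs$ratio_undefined[mm$epochs$epoch == "pre"])
  expect_true(is.na(mm$epochs$extension_retraction_ratio[mm$epochs$epoch == "pre"]))
})
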