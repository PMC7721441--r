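# Minimal hand-built events and tracks for geometry tests.
one_event <- function(footprint, peak_s = 100, amp = 10, id = 1L, ps = 1/3) {
  structure(tibble::tibble(event_id = id, peak_time_s = peak_s,
                           amplitude_pct = amp,
                           x_um = mean((footprint[, 2] - 1) * ps),
                           y_um = mean((footprint[, 1] - 1) * ps),
                           footprint = list(footprint)),
            pixel_size_um = ps, frame_interval_s = 0.3)
}

line_track <- function(x, y, dt = 0.3, id = 1L) {
  tibble::tibble(filo_id = id, frame = seq_along(x),
                 time_s = (seq_along(x) - 1) * dt,
                 tip_x_um = x, tip_y_um = y,
                 length_um = sqrt((x - x[1])^2 + (y - y[1])^2),
                 interpolated = FALSE)
}

disk_fp <- function(r0, c0, rad) {
  g <- expand.grid(r = (r0 - rad):(r0 + rad), c = (c0 - rad):(c0 + rad))
  as.matrix(g[(g$r - r0)^2 + (g$c - c0)^2 <= rad^2, ])
}

test_that("a tip at the event centroid overlaps from the first coincident frame", {
  fp <- disk_fp(30, 30, 5)
  ev <- one_event(fp)
  tip_xy <- c((30 - 1) / 3, (30 - 1) / 3)
  tk <- line_track(rep(tip_xy[1], 50), rep(tip_xy[2], 50))
  ov <- test_overlap(ev, tk)
  expect_true(ov$overlap)
  expect_equal(ov$entry_time_s, 0)
})

test_that("a far-away tip never overlaps", {
  ev <- one_event(disk_fp(10, 10, 3))
  tk <- line_track(rep(60, 50), rep(60, 50))
  ov <- test_overlap(ev, tk)
  expect_false(ov$overlap)
  expect_true(is.na(ov$entry_time_s))
})

test_that("entry time matches a brute-force per-frame membership scan", {
  fp <- disk_fp(30, 30, 4)
  ev <- one_event(fp)
  x <- seq(2, 18, length.out = 80)          # crosses the footprint boundary
  y <- rep((30 - 1) / 3, 80)
  tk <- line_track(x, y)
  ov <- test_overlap(ev, tk)
  inside <- vapply(seq_along(x), function(i) {
    r <- round(y[i] * 3) + 1; c <- round(x[i] * 3) + 1
    any(fp[, 1] == r & fp[, 2] == c)
  }, logical(1))
  expect_true(ov$overlap)
  expect_equal(ov$entry_time_s, (which(inside)[1] - 1) * 0.3)
})

test_that("an onset pairs with the nearest preceding peak in its domain", {
  fp <- disk_fp(30, 30, 5)
  ev <- one_event(fp, peak_s = 100)
  tip <- c((30 - 1) / 3, (30 - 1) / 3)
  n <- 600
  len <- c(seq(2, 8, length.out = 421), seq(8, 5, length.out = 180)[-1])
  tk <- line_track(rep(tip[1], n), rep(tip[2], n))
  tk$length_um <- len                       # retraction onset at frame 421 = 126 s
  on <- detect_motility_onsets(tk)
  rec <- pair_latencies(ev, tk, on)
  ret <- rec[rec$onset_type == "retraction", ]
  expect_equal(nrow(ret), 1)
  expect_equal(ret$paired_peak_time_s, 100)
  expect_equal(ret$latency_s, 26, tolerance = 0.5)
})

test_that("no overlapping events means an empty record list", {
  ev <- one_event(disk_fp(10, 10, 3))
  tk <- line_track(seq(50, 55, length.out = 60), rep(50, 60))
  rec <- pair_latencies(ev, tk)
  expect_equal(nrow(rec), 0)
})

test_that("ties on peak time resolve to the larger amplitude event", {
  fp <- disk_fp(30, 30, 5)
  e1 <- one_event(fp, peak_s = 100, amp = 8, id = 1L)
  e2 <- one_event(fp, peak_s = 100, amp = 20, id = 2L)
  ev <- structure(dplyr::bind_rows(e1, e2), pixel_size_um = 1/3,
                  frame_interval_s = 0.3)
  tip <- c((30 - 1) / 3, (30 - 1) / 3)
  tk <- line_track(rep(tip[1], 500), rep(tip[2], 500))
  tk$length_um <- c(rep(6, 400), 6 - 0.02 * (1:100))
  rec <- pair_latencies(ev, tk)
  ret <- rec[rec$onset_type == "retraction", ]
  expect_equal(ret$event_id, 2L)
})

test_that("perfect collinearity gives slope 1 and R^2 = 1; OLS matches normal equations", {
  rec <- tibble::tibble(onset_type = "retraction",
                        paired_peak_time_s = c(10, 50, 90, 130, 170),
                        onset_time_s = c(10, 50, 90, 130, 170) + 26,
                        latency_s = 26)
  fit <- onset_peak_regression(rec)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 26)

  set.seed(77)
  x <- c(12, 47, 88, 140, 201)
  y <- x + 26 + rnorm(5, 0, 3)
  rec2 <- tibble::tibble(onset_type = "retraction", paired_peak_time_s = x,
                         onset_time_s = y, latency_s = y - x)
  fit2 <- onset_peak_regression(rec2)
  # closed-form normal equations
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  r2 <- 1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  expect_equal(fit2$slope, b)
  expect_equal(fit2$intercept, a)
  expect_equal(fit2$r_squared, r2)
  expect_equal(glance(fit2)$r.squared, r2)
})

test_that("fewer than three records flags the regression as insufficient", {
  rec <- tibble::tibble(onset_type = "retraction",
                        paired_peak_time_s = c(10, 50),
                        onset_time_s = c(36, 76), latency_s = 26)
  fit <- onset_peak_regression(rec)
  expect_true(fit$insufficient)
  expect_true(is.na(fit$r_squared))
})

test_that("R^2 is invariant under a uniform time translation", {
  set.seed(78)
  x <- runif(30, 0, 300)
  y <- x + 26 + rnorm(30, 0, 2)
  rec <- tibble::tibble(onset_type = "retraction", paired_peak_time_s = x,
                        onset_time_s = y, latency_s = y - x)
  shifted <- dplyr::mutate(rec, paired_peak_time_s = paired_peak_time_s + 500,
                           onset_time_s = onset_time_s + 500)
  expect_equal(onset_peak_regression(rec)$r_squared,
               onset_peak_regression(shifted)$r_squared, tolerance = 1e-12)
})

test_that("events inside the inner radius are excluded from the bystander pool", {
  fp <- disk_fp(30, 30, 3)
  ev <- one_event(fp, peak_s = 50)
  # tip sits 5 um from the event centroid: closer than the 7.5 um annulus
  tip <- c((30 - 1) / 3 + 5, (30 - 1) / 3)
  tk <- line_track(rep(tip[1], 300), rep(tip[2], 300))
  tk$length_um <- c(rep(5, 200), 5 - 0.03 * (1:100))
  bc <- bystander_control(ev, tk)
  expect_equal(bc$n, 0)
  expect_equal(formals(bystander_control)$inner_radius_um, 7.5)
  # at 10 um the same event is a legitimate bystander
  tk2 <- line_track(rep((30 - 1) / 3 + 10, 300), rep(tip[2], 300))
  tk2$length_um <- tk$length_um
  bc2 <- bystander_control(ev, tk2)
  expect_equal(bc2$n, 1)
})

test_that("uncoupled events show no onset-peak correlation (bootstrap null)", {
  set.seed(79)
  recs <- list()
  for (rep in 1:6) {
    n <- 25
    ev_t <- runif(n, 0, 300)
    onset_t <- runif(n, 0, 300)
    ps <- 1/3
    evs <- dplyr::bind_rows(lapply(seq_len(n), function(i)
      one_event(disk_fp(20 + 3 * i, 20, 2), peak_s = ev_t[i], id = i)))
    evs <- structure(evs, pixel_size_um = ps, frame_interval_s = 0.3)
    recs[[rep]] <- tibble::tibble(
      event_id = seq_len(n), filo_id = 1L, onset_type = "retraction",
      onset_time_s = sort(onset_t),
      paired_peak_time_s = ev_t[order(runif(n))],
      latency_s = 1)
  }
  # correlation of unrelated peak times with onsets: interval spans 0
  pooled <- dplyr::bind_rows(recs)
  boots <- replicate(200, {
    j <- sample(nrow(pooled), replace = TRUE)
    cor(pooled$paired_peak_time_s[j], pooled$onset_time_s[j])
  })
  ci <- quantile(boots, c(0.025, 0.975))
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("coupling summary reports full overlap and the forced interval ordering", {
  fp <- disk_fp(30, 30, 5)
  ev <- one_event(fp, peak_s = 100)
  tip <- c((30 - 1) / 3, (30 - 1) / 3)
  n <- 799
  # retraction onset at 126 s (latency 26 s), then a late re-extension
  # whose onset sits much further from the peak
  len <- c(seq(2, 8, length.out = 421), seq(8, 5, length.out = 180)[-1],
           seq(5, 7, length.out = 200)[-1])
  tk <- line_track(rep(tip[1], n), rep(tip[2], n))
  tk$length_um <- len
  rec <- pair_latencies(ev, tk, max_lag_s = 200)
  cs <- coupling_summary(rec, tk, ev)
  expect_equal(cs$fraction_tips_overlapping, 1)
  # extension onset (trace start) sits much further from the peak than the
  # retraction onset that follows it
  expect_gt(cs$extension_interval$mean, cs$retraction_latency$mean)
  g <- glance(cs)
  expect_equal(g$n_tips, 1)
})

test_that("overlap fraction recovers a designed coupling probability (binomial check)", {
  cfg <- sim_config(duration_s = 360, field_size_um = c(220, 220),
                    n_hotspots = 90, events_per_hotspot_range = c(1, 1),
                    n_filopodia = 120, noise_sd = 0,
                    category_proportions = c(0, 0.25, 0.5, 0.25),
                    coupling_enabled = TRUE, seed = 81)
  ev <- simulate_events(cfg)
  gt <- simulate_filopodia(cfg, ev)
  ca <- gt_events_as_ca(ev, cfg$pixel_size_um, filocal:::field_px_of(cfg))
  tips <- data.frame(filo_id = gt$frames$filo_id, frame = gt$frames$frame,
                     time_s = gt$frames$time_s, x_um = gt$frames$tip_x_um,
                     y_um = gt$frames$tip_y_um)
  tk <- track_tips(tips = tips)
  attr(tk, "pixel_size_um") <- cfg$pixel_size_um
  ov <- test_overlap(ca, tk)
  frac <- length(unique(ov$filo_id[ov$overlap])) / 120
  p_design <- mean(gt$filopodia$coupled)
  expect_gte(p_design, 0.4)   # the designed coupling succeeded for most draws
  # recovered fraction within the binomial 95% interval around the design
  ci <- p_design + c(-1.96, 1.96) * sqrt(p_design * (1 - p_design) / 120)
  expect_gte(frac, ci[1])
  # chance overlap can only add; allow the upper bound a small margin
  expect_lte(frac, ci[2] + 0.1)
})
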