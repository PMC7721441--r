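filo_categories <- c("extension", "retraction", "extension_and_retraction",
                     "stationary")

# Distance from points (px, py) to segment p0-p1.
seg_point_dist <- function(px, py, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) return(sqrt((px - p0[1])^2 + (py - p0[2])^2))
  tt <- pmin(1, pmax(0, ((px - p0[1]) * vx + (py - p0[2]) * vy) / len2))
  sqrt((px - (p0[1] + tt * vx))^2 + (py - (p0[2] + tt * vy))^2)
}

# Minimum distance between two 2D segments.
seg_seg_dist <- function(a0, a1, b0, b1) {
  d <- function(p, q0, q1) seg_point_dist(p[1], p[2], q0, q1)
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  s1 <- cross(a0, a1, b0); s2 <- cross(a0, a1, b1)
  s3 <- cross(b0, b1, a0); s4 <- cross(b0, b1, a1)
  if (((s1 > 0) != (s2 > 0)) && ((s3 > 0) != (s4 > 0))) return(0)
  min(d(b0, a0, a1), d(b1, a0, a1), d(a0, b0, b1), d(a1, b0, b1))
}

# Length trace (um) for one motility program, sampled at frame times.
filo_length_trace <- function(t, category, len0, v_ext, v_ret,
                              ext_onset_s = NA, ret_onset_s = NA,
                              len_cap = Inf, len_floor = 1) {
  len <- switch(category,
    stationary = rep(len0, length(t)),
    extension = pmin(len0 + v_ext * pmax(0, t - ext_onset_s), len_cap),
    retraction = len0 - v_ret * pmax(0, t - ret_onset_s),
    extension_and_retraction = {
      # growth saturates at the cap; retraction resumes from the capped
      # length at the injected onset
      up <- pmin(len0 + v_ext * pmax(0, pmin(t, ret_onset_s) - ext_onset_s),
                 len_cap)
      up - v_ret * pmax(0, t - ret_onset_s)
    })
  pmin(pmax(len, len_floor), len_cap)
}

#' Draw the ground-truth filopodium cohort for a configuration
#'
#' Assigns each filopodium a motility category (seeded draw with the
#' configured proportions), an anchored base, an orientation and a length
#' program, and -- when coupling is enabled -- steers each
#' extension-and-retraction filopodium so its tip reaches the centre of a
#' dedicated Ca2+ event at that event's peak time, with the injected
#' retraction onset at `peak + coupling_latency_s + jitter`. A filopodium
#' for which no event can be reached inside the field is rendered uncoupled
#' and flagged.
#'
#' @param cfg A [sim_config()].
#' @param events Ground-truth event table from [simulate_events()]
#'   (required when `cfg$coupling_enabled`).
#' @return A list with `filopodia` (one row per filopodium: base,
#'   orientation, category, onsets, coupling) and `frames` (per-frame true
#'   tip position and length).
#' @export
simulate_filopodia <- function(cfg, events = NULL) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n_filopodia
  empty <- list(
    filopodia = tibble(filo_id = integer(), category = character(),
                       base_x_um = numeric(), base_y_um = numeric(),
                       orientation_deg = numeric(), initial_length_um = numeric(),
                       extension_onset_s = numeric(), retraction_onset_s = numeric(),
                       coupled = logical(), coupled_event_id = integer(),
                       coupling_flagged = logical()),
    frames = tibble(filo_id = integer(), frame = integer(), time_s = numeric(),
                    tip_x_um = numeric(), tip_y_um = numeric(),
                    length_um = numeric()))
  if (n == 0) return(empty)
  if (cfg$coupling_enabled && (is.null(events) || nrow(events) == 0)) {
    abort("coupling is enabled but no ground-truth events were supplied.")
  }

  w <- cfg$field_size_um[1]; h <- cfg$field_size_um[2]
  margin <- 1.2
  stub <- 2.5                   # parent-branch half-length either side, um
  len_floor <- 2.2   # keep retracted stubs resolvable by the tracker
  v_ext <- cfg$extension_rate_um_per_min / 60
  v_ret <- cfg$retraction_rate_um_per_min / 60
  t <- (seq_len(n_frames_of(cfg)) - 1) * cfg$frame_interval_s
  dur <- cfg$duration_s

  with_seed(child_seed(cfg$seed, 3L), {
    category <- sample(filo_categories, n, replace = TRUE,
                       prob = cfg$category_proportions)
    len0 <- runif(n, 4, 7)
    jitter <- rnorm(n, 0, cfg$coupling_jitter_sd_s)

    placed <- list()   # per accepted structure: list of its segments
    in_field <- function(p) p[1] >= margin && p[1] <= w - margin &&
      p[2] >= margin && p[2] <= h - margin
    separated <- function(segs) {
      for (old in placed) {
        for (s1 in segs) for (s2 in old) {
          if (seg_seg_dist(s1[[1]], s1[[2]], s2[[1]], s2[[2]]) < 1.2) return(FALSE)
        }
      }
      TRUE
    }
    # a structure is the filopodium (base -> maximal tip) plus the static
    # parent branch drawn perpendicular through its base
    structure_segs <- function(b, dirv, l_max) {
      perp <- c(-dirv[2], dirv[1])
      list(list(b - stub * perp, b + stub * perp),
           list(b, b + l_max * dirv))
    }
    # keep the tip path clear of every event footprint except its own
    # target, so each onset has one unambiguous preceding event
    clear_of_events <- function(segs, exclude_id = NA_integer_) {
      if (is.null(events) || nrow(events) == 0) return(TRUE)
      oth <- events[is.na(exclude_id) | events$event_id != exclude_id, ]
      for (k in seq_len(nrow(oth))) {
        dmin <- min(seg_point_dist(oth$x_um[k], oth$y_um[k],
                                   segs[[2]][[1]], segs[[2]][[2]]))
        if (dmin < oth$radius_um[k] + 1) return(FALSE)
      }
      TRUE
    }

    avail_events <- if (!is.null(events) && nrow(events)) {
      ev <- events[events$peak_time_s >= 40 & events$peak_time_s <= dur - 35, ]
      ev[sample(nrow(ev)), ]
    } else NULL

    info <- vector("list", n)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- category[i]
      ext_on <- if (cat_i %in% c("extension", "extension_and_retraction")) 0 else NA_real_
      ret_on <- switch(cat_i,
        retraction = runif(1, 5, 60),
        extension_and_retraction = runif(1, 0.35 * dur, 0.8 * dur),
        NA_real_)
      coupled <- FALSE; coupled_ev <- NA_integer_; flagged <- FALSE
      base <- NULL; theta <- NULL; cap <- Inf

      if (cfg$coupling_enabled && cat_i == "extension_and_retraction") {
        # steer the tip into a dedicated event: tip at the event centroid at
        # its peak, retraction injected at peak + latency + jitter
        while (!coupled && !is.null(avail_events) && nrow(avail_events) > 0) {
          ev <- avail_events[1, ]
          avail_events <- avail_events[-1, ]
          onset_try <- ev$peak_time_s + cfg$coupling_latency_s + jitter[i]
          if (onset_try <= ev$peak_time_s || onset_try >= dur - 5) next
          reach <- len0[i] + v_ext * ev$peak_time_s
          l_max <- len0[i] + v_ext * onset_try
          for (try in 1:60) {
            th <- runif(1, 0, 2 * pi)
            dirv <- c(cos(th), sin(th))
            b <- c(ev$x_um, ev$y_um) - reach * dirv
            segs <- structure_segs(b, dirv, l_max)
            ends <- c(list(b), lapply(segs, `[[`, 1), lapply(segs, `[[`, 2))
            if (all(vapply(ends, in_field, logical(1))) && separated(segs) &&
                clear_of_events(segs, ev$event_id)) {
              base <- b; theta <- th; ret_on <- onset_try
              coupled <- TRUE; coupled_ev <- ev$event_id
              placed[[length(placed) + 1L]] <- segs
              break
            }
          }
        }
        if (!coupled) flagged <- TRUE
      }

      if (is.null(base)) {  # uncoupled placement
        l_max <- switch(cat_i,
          stationary = len0[i],
          retraction = len0[i],
          extension = len0[i] + v_ext * dur,
          extension_and_retraction = len0[i] + v_ext * ret_on)
        for (try in 1:300) {
          th <- runif(1, 0, 2 * pi)
          dirv <- c(cos(th), sin(th))
          b <- c(runif(1, margin, w - margin), runif(1, margin, h - margin))
          cap_try <- Inf
          if (!in_field(b + l_max * dirv)) {
            # cap growth where the tip would leave the inset field
            cap_try <- max_len_inside(b, dirv, w, h, margin)
            if (cap_try < len0[i]) next
          }
          segs <- structure_segs(b, dirv, min(l_max, cap_try))
          ends <- c(lapply(segs, `[[`, 1), lapply(segs, `[[`, 2))
          if (all(vapply(ends, in_field, logical(1))) && separated(segs) &&
              clear_of_events(segs)) {
            base <- b; theta <- th; cap <- cap_try
            placed[[length(placed) + 1L]] <- segs
            break
          }
        }
        if (is.null(base)) {
          abort("could not place filopodia without collisions; reduce `n_filopodia`.")
        }
      }

      lens <- filo_length_trace(t, cat_i, len0[i], v_ext, v_ret,
                                ext_onset_s = ext_on, ret_onset_s = ret_on,
                                len_cap = cap, len_floor = len_floor)
      dirv <- c(cos(theta), sin(theta))
      info[[i]] <- tibble(
        filo_id = i, category = cat_i, base_x_um = base[1], base_y_um = base[2],
        orientation_deg = theta * 180 / pi, initial_length_um = len0[i],
        extension_onset_s = ext_on, retraction_onset_s = ret_on,
        coupled = coupled, coupled_event_id = coupled_ev,
        coupling_flagged = flagged)
      frames[[i]] <- tibble(
        filo_id = i, frame = seq_along(t), time_s = t,
        tip_x_um = base[1] + lens * dirv[1],
        tip_y_um = base[2] + lens * dirv[2],
        length_um = lens)
    }
    list(filopodia = dplyr::bind_rows(info), frames = dplyr::bind_rows(frames))
  })
}

# Largest length along direction `dirv` from `b` keeping the tip inside the
# field inset by `margin`.
max_len_inside <- function(b, dirv, w, h, margin) {
  lim <- Inf
  if (dirv[1] > 0) lim <- min(lim, (w - margin - b[1]) / dirv[1])
  if (dirv[1] < 0) lim <- min(lim, (margin - b[1]) / dirv[1])
  if (dirv[2] > 0) lim <- min(lim, (h - margin - b[2]) / dirv[2])
  if (dirv[2] < 0) lim <- min(lim, (margin - b[2]) / dirv[2])
  lim
}

# Rasterize an anti-aliased segment of a given width onto `img` (px coords,
# pixel centres at integers); returns the updated matrix.
render_segment <- function(img, p0, p1, width_px = 2, intensity = 1000) {
  half <- width_px / 2
  r0 <- max(1L, floor(min(p0[2], p1[2]) - half - 1))
  r1 <- min(nrow(img), ceiling(max(p0[2], p1[2]) + half + 1))
  c0 <- max(1L, floor(min(p0[1], p1[1]) - half - 1))
  c1 <- min(ncol(img), ceiling(max(p0[1], p1[1]) + half + 1))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  px <- rep(cols, each = length(rows)); py <- rep(rows, times = length(cols))
  d <- seg_point_dist(px, py, p0, p1)
  cov <- pmin(1, pmax(0, half + 0.5 - d))
  block <- matrix(cov * intensity, nrow = length(rows))
  img[rows, cols] <- pmax(img[rows, cols], block)
  img
}

#' Render the trachea membrane channel
#'
#' Draws, for every filopodium, a static 5 um parent branch perpendicular
#' through its base plus a 2 px wide anti-aliased segment from the anchored
#' base to the moving tip, on a dark background, then adds Gaussian noise.
#' The branch-filopodium junction makes the base detectable from the image
#' alone, and the ~1 px intensity taper at the tip end of the line is what
#' allows the tracker to localize tips at sub-pixel precision.
#'
#' @inheritParams simulate_filopodia
#' @param filopodia Optional precomputed output of [simulate_filopodia()].
#' @return A list with `movie` (a [movie_stack()]), `filopodia` and
#'   `frames` ground-truth tables.
#' @export
generate_trachea_movie <- function(cfg, events = NULL, filopodia = NULL) {
  cfg <- validate_sim_config(cfg)
  gt <- filopodia %||% simulate_filopodia(cfg, events)
  nf <- n_frames_of(cfg)
  fp <- field_px_of(cfg)
  ps <- cfg$pixel_size_um
  stub <- 2.5

  arr <- array(0, c(nf, fp[["height"]], fp[["width"]]))
  if (nrow(gt$filopodia) > 0) {
    fr <- dplyr::arrange(gt$frames, .data$frame, .data$filo_id)
    per_frame <- split(fr, fr$frame)
    branch_img <- matrix(0, fp[["height"]], fp[["width"]])
    for (i in seq_len(nrow(gt$filopodia))) {
      fi <- gt$filopodia[i, ]
      dirv <- c(cos(fi$orientation_deg * pi / 180),
                sin(fi$orientation_deg * pi / 180))
      perp <- c(-dirv[2], dirv[1])
      b_um <- c(fi$base_x_um, fi$base_y_um)
      branch_img <- render_segment(branch_img,
                                   (b_um - stub * perp) / ps + 1,
                                   (b_um + stub * perp) / ps + 1,
                                   width_px = 2,
                                   intensity = cfg$baseline_intensity)
    }
    for (k in seq_len(nf)) {
      img <- branch_img
      fk <- per_frame[[k]]
      for (i in seq_len(nrow(gt$filopodia))) {
        fi <- gt$filopodia[i, ]
        base_px <- c(fi$base_x_um, fi$base_y_um) / ps + 1
        tip_px <- c(fk$tip_x_um[i], fk$tip_y_um[i]) / ps + 1
        img <- render_segment(img, base_px, tip_px, width_px = 2,
                              intensity = cfg$baseline_intensity)
      }
      arr[k, , ] <- img
    }
  }
  arr <- with_seed(child_seed(cfg$seed, 4L), {
    if (cfg$noise_sd > 0) arr <- arr + rnorm(length(arr), 0, cfg$noise_sd)
    arr
  })
  arr <- round(pmax(arr, 0))
  if (max(arr) > 65535) {
    warn("rendered intensities exceed the 16-bit range; rescaling to fit.")
    arr <- round(arr * (65535 / max(arr)))
  }
  dim(arr) <- c(nf, fp[["height"]], fp[["width"]])
  list(movie = movie_stack(arr, cfg$frame_interval_s, ps, channel = "trachea"),
       filopodia = gt$filopodia, frames = gt$frames)
}
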