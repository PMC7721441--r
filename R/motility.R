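# Residual sum of squares of a straight-line fit (0 for < 3 points).
line_rss <- function(x, y) {
  if (length(x) < 3) return(0)
  sum(stats::lm.fit(cbind(1, x), y)$residuals^2)
}

# Localize a motility onset as the breakpoint of a two-segment linear fit
# inside a window around the hysteresis anchor: the corner index j that
# minimizes RSS(line on lo..j) + RSS(line on j..hi). Ties resolve to the
# earliest candidate, so a trace that declines from its first frame scores
# its onset there.
refine_breakpoint <- function(len, lo, hi) {
  cands <- lo:max(lo, hi - 2L)
  x <- as.numeric(seq_along(len))
  rss <- vapply(cands, function(j) {
    line_rss(x[lo:j], len[lo:j]) + line_rss(x[j:hi], len[j:hi])
  }, numeric(1))
  # floating-point ties (e.g. an exactly linear trace) resolve to the
  # earliest candidate
  cands[which(rss <= min(rss) + 1e-10)[1]]
}

# Hysteresis (zigzag) segmentation of one length trace. A run is confirmed
# once it accumulates `min_change` um over at least `min_frames` frames;
# its onset is then localized by two-line breakpoint refinement around the
# run's starting extremum. Within an ongoing run, a stall (>= min_frames
# frames without a new extremum) followed by a further change of
# `min_change` opens a distinct onset, so runs separated by sub-threshold
# plateaus are scored separately.
zigzag_onsets <- function(len, min_change, min_frames, stall_frames = NULL) {
  n <- length(len)
  res <- list()
  if (n < 2) return(res)
  stall_frames <- max(min_frames, stall_frames %||% (5L * min_frames))
  win_back <- max(15L, 3L * min_frames)
  prev_bound <- 1L
  emit <- function(type, anchor, confirm_i) {
    lo_w <- max(prev_bound, anchor - win_back)
    hi_w <- min(n, confirm_i + 5L)
    j <- refine_breakpoint(len, lo_w, hi_w)
    res[[length(res) + 1L]] <<- list(type = type, onset_i = j)
    prev_bound <<- j
  }

  mode <- 0L
  hi_i <- 1L; lo_i <- 1L     # running extremes since the last mode switch
  anti_hi <- 1L; anti_lo <- 1L  # counter-extreme since the last extreme
  stalled <- FALSE
  for (i in 2:n) {
    # stall: no new extremum in the run's direction for stall_frames frames
    if (mode == -1L && i - lo_i >= stall_frames) stalled <- TRUE
    if (mode == 1L && i - hi_i >= stall_frames) stalled <- TRUE

    new_max <- FALSE; new_min <- FALSE
    if (mode != -1L) {
      if (len[i] > len[hi_i]) {
        hi_i <- i
        new_max <- TRUE
      }
      if (len[hi_i] - len[i] >= min_change && i - hi_i >= min_frames - 1L) {
        emit("retraction", hi_i, i)
        mode <- -1L; lo_i <- i; anti_hi <- i; stalled <- FALSE
        next
      }
    }
    if (mode != 1L) {
      if (len[i] < len[lo_i]) {
        lo_i <- i
        new_min <- TRUE
      }
      if (len[i] - len[lo_i] >= min_change && i - lo_i >= min_frames - 1L) {
        emit("extension", lo_i, i)
        mode <- 1L; hi_i <- i; anti_lo <- i; stalled <- FALSE
        next
      }
    }
    if (mode == -1L) {
      if (new_min) {
        if (stalled && len[anti_hi] - len[i] >= min_change) {
          emit("retraction", anti_hi, i)
          stalled <- FALSE
          anti_hi <- i
        } else if (!stalled) anti_hi <- i  # keep the stall max as anchor
      } else if (len[i] > len[anti_hi]) anti_hi <- i
    } else if (mode == 1L) {
      if (new_max) {
        if (stalled && len[i] - len[anti_lo] >= min_change) {
          emit("extension", anti_lo, i)
          stalled <- FALSE
          anti_lo <- i
        } else if (!stalled) anti_lo <- i
      } else if (len[i] < len[anti_lo]) anti_lo <- i
    }
  }
  # close each motile segment at the next onset, or at the first index
  # attaining the final run's extremum
  if (length(res)) {
    for (j in seq_along(res)) {
      start <- res[[j]]$onset_i
      if (j < length(res)) {
        res[[j]]$end_i <- res[[j + 1L]]$onset_i
      } else {
        rng <- start:n
        res[[j]]$end_i <- if (res[[j]]$type == "retraction") {
          rng[which.min(len[rng])]
        } else {
          rng[which.max(len[rng])]
        }
      }
    }
  }
  res
}

#' Detect extension and retraction onsets in filopodial length traces
#'
#' Scans each filopodium's length trace with a hysteresis rule: a
#' retraction onset is scored where a run of frames first accumulates a
#' length decrease of at least `min_change_um` over at least `min_frames`
#' frames, and the onset is placed at the preceding length maximum (centre
#' of an exact plateau); extension onsets are symmetric. Runs separated by
#' sub-threshold plateaus of at least `min_stall_s` yield distinct onsets.
#' Raising `min_change_um` never increases the number of onsets.
#'
#' @param tracks A `filo_tracks` tibble from [track_tips()].
#' @param min_change_um Hysteresis: cumulative length change, um.
#' @param min_frames Hysteresis: minimum run duration, frames.
#' @param min_stall_s Minimum pause, in seconds, without a new run extremum
#'   before a resumed run is scored as a distinct onset.
#' @return Tibble with one row per onset: `filo_id`, `onset_type`
#'   (`"extension"` / `"retraction"`), `onset_frame`, `onset_time_s`,
#'   `end_frame`, `delta_um` (signed length change over the motile
#'   segment), `rate_um_per_min` (positive magnitude).
#' @export
detect_motility_onsets <- function(tracks, min_change_um = 0.5,
                                   min_frames = 3, min_stall_s = 5) {
  out <- tracks |>
    dplyr::arrange(.data$filo_id, .data$frame) |>
    dplyr::group_by(.data$filo_id) |>
    dplyr::group_map(function(tr, key) {
      dt <- stats::median(diff(tr$time_s))
      stall_frames <- if (is.finite(dt) && dt > 0)
        as.integer(ceiling(min_stall_s / dt)) else 5L * min_frames
      segs <- zigzag_onsets(tr$length_um, min_change_um, min_frames,
                            stall_frames = stall_frames)
      if (!length(segs)) return(NULL)
      dplyr::bind_rows(lapply(segs, function(s) {
        dt_min <- (tr$time_s[s$end_i] - tr$time_s[s$onset_i]) / 60
        tibble(filo_id = key$filo_id, onset_type = s$type,
               onset_frame = tr$frame[s$onset_i],
               onset_time_s = tr$time_s[s$onset_i],
               end_frame = tr$frame[s$end_i],
               delta_um = tr$length_um[s$end_i] - tr$length_um[s$onset_i],
               rate_um_per_min = if (dt_min > 0)
                 abs(tr$length_um[s$end_i] - tr$length_um[s$onset_i]) / dt_min
               else NA_real_)
      }))
    }) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(filo_id = integer(), onset_type = character(),
                  onset_frame = integer(), onset_time_s = numeric(),
                  end_frame = integer(), delta_um = numeric(),
                  rate_um_per_min = numeric())
  }
  out
}

#' Classify filopodium motility
#'
#' Assigns each track to one of the four motility categories from its
#' detected onsets: only extension onsets gives `"extension"`, only
#' retraction `"retraction"`, both `"extension_and_retraction"`, neither
#' `"stationary"`. Also summarises per-track rates and maximum length.
#'
#' @param tracks A `filo_tracks` tibble.
#' @param onsets Onset table from [detect_motility_onsets()]; computed with
#'   defaults when missing.
#' @return Tibble with one row per filopodium: `filo_id`, `category`,
#'   onset counts, mean extension/retraction rates (um/min; `NA` when the
#'   track has no such segment), `max_length_um`.
#' @export
classify_tracks <- function(tracks, onsets = NULL) {
  onsets <- onsets %||% detect_motility_onsets(tracks)
  per_track <- tracks |>
    dplyr::summarise(max_length_um = max(.data$length_um), .by = "filo_id")
  ocounts <- onsets |>
    dplyr::summarise(
      n_extension = sum(.data$onset_type == "extension"),
      n_retraction = sum(.data$onset_type == "retraction"),
      mean_extension_rate_um_per_min =
        mean(.data$rate_um_per_min[.data$onset_type == "extension"]),
      mean_retraction_rate_um_per_min =
        mean(.data$rate_um_per_min[.data$onset_type == "retraction"]),
      .by = "filo_id")
  per_track |>
    dplyr::left_join(ocounts, by = "filo_id") |>
    dplyr::mutate(
      n_extension = tidyr::replace_na(.data$n_extension, 0L),
      n_retraction = tidyr::replace_na(.data$n_retraction, 0L),
      category = dplyr::case_when(
        .data$n_extension > 0 & .data$n_retraction > 0 ~ "extension_and_retraction",
        .data$n_extension > 0 ~ "extension",
        .data$n_retraction > 0 ~ "retraction",
        .default = "stationary")) |>
    dplyr::relocate("filo_id", "category") |>
    dplyr::arrange(.data$filo_id)
}

#' @rdname classify_tracks
#' @param track_onsets Onset rows of a single track.
#' @export
classify_track <- function(track_onsets) {
  has_ext <- any(track_onsets$onset_type == "extension")
  has_ret <- any(track_onsets$onset_type == "retraction")
  if (has_ext && has_ret) "extension_and_retraction"
  else if (has_ext) "extension"
  else if (has_ret) "retraction"
  else "stationary"
}

#' Cohort motility metrics
#'
#' Cohort mean +/- SEM of extension and retraction rates and maximum
#' lengths, the category breakdown, and -- when `epoch_split_s` is given --
#' the extension:retraction onset-count ratio in the pre and post epochs
#' and its post/pre change. An epoch with zero retraction onsets has an
#' undefined ratio (flagged `NA`, never reported as 0).
#'
#' @param tracks A `filo_tracks` tibble.
#' @param onsets Onset table; computed with defaults when missing.
#' @param epoch_split_s Optional epoch boundary, seconds.
#' @return List of class `motility_metrics`: `rates` (tibble of cohort
#'   means), `categories` (counts and fractions), `summary` (per-track
#'   table), and optionally `epochs`.
#' @export
motility_metrics <- function(tracks, onsets = NULL, epoch_split_s = NULL) {
  onsets <- onsets %||% detect_motility_onsets(tracks)
  summary <- classify_tracks(tracks, onsets)
  ext <- mean_sem(summary$mean_extension_rate_um_per_min)
  ret <- mean_sem(summary$mean_retraction_rate_um_per_min)
  len <- mean_sem(summary$max_length_um)
  rates <- tibble(
    metric = c("extension_rate_um_per_min", "retraction_rate_um_per_min",
               "max_length_um"),
    mean = c(ext$mean, ret$mean, len$mean),
    sem = c(ext$sem, ret$sem, len$sem),
    n = c(ext$n, ret$n, len$n))
  categories <- tibble(category = filo_categories) |>
    dplyr::left_join(dplyr::count(summary, .data$category), by = "category") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L),
                  fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_)
  out <- list(rates = rates, categories = categories, summary = summary)
  if (!is.null(epoch_split_s)) {
    ratio_of <- function(o) {
      ne <- sum(o$onset_type == "extension")
      nr <- sum(o$onset_type == "retraction")
      list(n_extension = ne, n_retraction = nr,
           ratio = if (nr > 0) ne / nr else NA_real_,
           undefined = nr == 0)
    }
    pre <- ratio_of(onsets[onsets$onset_time_s < epoch_split_s, ])
    post <- ratio_of(onsets[onsets$onset_time_s >= epoch_split_s, ])
    out$epochs <- tibble(
      epoch = c("pre", "post"),
      n_extension = c(pre$n_extension, post$n_extension),
      n_retraction = c(pre$n_retraction, post$n_retraction),
      extension_retraction_ratio = c(pre$ratio, post$ratio),
      ratio_undefined = c(pre$undefined, post$undefined))
    out$ratio_change <- if (!pre$undefined && !post$undefined && pre$ratio > 0)
      post$ratio / pre$ratio else NA_real_
  }
  structure(out, class = "motility_metrics")
}

#' @export
print.motility_metrics <- function(x, ...) {
  cat("<motility_metrics>\n")
  print(x$rates)
  print(x$categories)
  invisible(x)
}
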