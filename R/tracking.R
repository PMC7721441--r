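# --- low-level binary image ops ---------------------------------------------

# Otsu's threshold on a numeric image (256-bin histogram).
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1] + 1)  # flat image: nothing foreground
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(img, breaks, all.inside = TRUE), nbins = 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

shift_mat <- function(m, dr, dc) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
  ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# Zhang-Suen thinning of a logical matrix down to a 1 px skeleton.
zhang_suen <- function(mask) {
  p <- mask
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in the standard order p2..p9 (N, NE, E, SE, S, SW, W, NW)
      n <- list(shift_mat(p, -1, 0), shift_mat(p, -1, 1), shift_mat(p, 0, 1),
                shift_mat(p, 1, 1), shift_mat(p, 1, 0), shift_mat(p, 1, -1),
                shift_mat(p, 0, -1), shift_mat(p, -1, -1))
      b <- Reduce(`+`, n)
      a <- matrix(0L, nrow(p), ncol(p))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        a <- a + (!n[[i]] & n[[j]])
      }
      cond <- p & b >= 2 & b <= 6 & a == 1
      if (step == 1) {
        cond <- cond & !(n[[1]] & n[[3]] & n[[5]]) & !(n[[3]] & n[[5]] & n[[7]])
      } else {
        cond <- cond & !(n[[1]] & n[[3]] & n[[7]]) & !(n[[1]] & n[[5]] & n[[7]])
      }
      if (any(cond)) {
        p[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p
}

neighbour_count_8 <- function(mask) {
  s <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr || dc) s <- s + shift_mat(mask, dr, dc)
  }
  s
}

stencil_2d8 <- function() {
  rbind(c(0, 0, 1), c(0, 1, -1), c(0, 1, 0), c(0, 1, 1))
}

# 8-connected labelling of a logical matrix; returns a list with `coords`
# (row, col) and `membership`.
label_2d <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(list(coords = cbind(integer(), integer()),
                                membership = integer()))
  co <- arrayInd(idx, dim(mask))
  memb <- sparse_components(cbind(1L, co), stencil_2d8(),
                            c(1L, dim(mask)))
  list(coords = co, membership = memb)
}

# Sub-pixel tip refinement: walk a few skeleton steps back from the
# endpoint to get the local direction, then find where the intensity along
# the outgoing ray falls to half of the line's plateau. The rendered /
# imaged line tapers over about `tip_offset_px` beyond the true end, which
# is subtracted.
refine_tip <- function(img, skel, end_rc, tip_offset_px = 1) {
  path <- matrix(end_rc, nrow = 1)
  cur <- end_rc; prev <- c(NA, NA)
  for (step in 1:4) {
    nb <- NULL
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- cur[1] + dr; c <- cur[2] + dc
      if (r < 1 || c < 1 || r > nrow(skel) || c > ncol(skel)) next
      if (skel[r, c] && !(identical(c(r, c), prev)) &&
          !any(path[, 1] == r & path[, 2] == c)) nb <- rbind(nb, c(r, c))
    }
    if (is.null(nb) || nrow(nb) != 1) break
    prev <- cur; cur <- nb[1, ]
    path <- rbind(path, cur)
  }
  if (nrow(path) < 2) return(c(end_rc[2], end_rc[1]))  # (x, y) fallback
  v <- end_rc - path[nrow(path), ]                     # points outward
  v <- v / sqrt(sum(v^2))
  ss <- seq(-2, 3, by = 0.05)
  vals <- bilinear_at(img, end_rc[1] + ss * v[1], end_rc[2] + ss * v[2])
  plateau <- stats::median(vals[ss <= -1])
  if (!is.finite(plateau) || plateau <= 0) return(c(end_rc[2], end_rc[1]))
  below <- which(ss > -1 & vals < plateau / 2)
  if (!length(below)) return(c(end_rc[2], end_rc[1]))
  s_half <- ss[below[1]]
  tip_rc <- end_rc + (s_half - tip_offset_px) * v
  c(tip_rc[2], tip_rc[1])                              # return (x, y) in px
}

bilinear_at <- function(img, r, c) {
  r <- pmin(pmax(r, 1), nrow(img)); c <- pmin(pmax(c, 1), ncol(img))
  r0 <- pmin(floor(r), nrow(img) - 1); c0 <- pmin(floor(c), ncol(img) - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# --- tracker -----------------------------------------------------------------

#' Track filopodial tips through a trachea-channel movie
#'
#' Per frame, the movie is binarized (Otsu's threshold by default, or a
#' fixed override), small specks are discarded, each connected structure is
#' skeletonized and its skeleton endpoints and junctions located. A
#' structure is one filopodium with its parent branch: the branch-filopodium
#' junction anchors the base, the branch's two arms point in opposite
#' directions, and the remaining endpoint is the tip. Tips are linked
#' across frames by nearest-neighbour continuity (ambiguous links, with two
#' candidates inside the step tolerance, resolve to the nearest and are
#' counted), localized to sub-pixel precision from the intensity taper at
#' the line end, and structures observed for fewer than
#' `min_lifetime_frames` frames are dropped. Missing frames inside a
#' track's lifetime are filled by linear interpolation.
#'
#' Alternatively, a precomputed tip table can be supplied via `tips`
#' (columns `filo_id`, `frame`, `x_um`, `y_um`, optionally `base_x_um`,
#' `base_y_um`), in which case all imaging steps are skipped; without base
#' columns, lengths are measured from each filopodium's first-frame tip
#' position.
#'
#' @param movie A trachea-channel [movie_stack()] (ignored when `tips` is
#'   given).
#' @param threshold Fixed binarization threshold; `NULL` uses Otsu per
#'   frame.
#' @param max_step_um Maximum expected tip movement per frame, um; larger
#'   jumps count as ambiguous links.
#' @param min_lifetime_frames Minimum track lifetime, frames.
#' @param min_component_px Discard connected components smaller than this.
#' @param tip_offset_px Taper length subtracted along the ray when
#'   localizing the tip (matched to a ~2 px wide anti-aliased line).
#' @param tips Optional precomputed tip table (see above).
#' @return A tibble of class `filo_tracks`, one row per (filopodium,
#'   frame): `filo_id`, `frame`, `time_s`, `tip_x_um`, `tip_y_um`,
#'   `length_um`, `interpolated`. Per-track base anchors are in the
#'   `bases` attribute; `n_ambiguous_links` records how many links needed a
#'   nearest-candidate tie-break.
#' @export
track_tips <- function(movie = NULL, threshold = NULL, max_step_um = 2,
                       min_lifetime_frames = 10, min_component_px = 10,
                       tip_offset_px = 1, tips = NULL) {
  if (!is.null(tips)) {
    fi <- if (inherits(movie, "movie_stack")) movie$frame_interval_s else NULL
    return(tracks_from_table(tips, frame_interval_s = fi))
  }
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  ps <- movie$pixel_size_um
  dt <- movie$frame_interval_s
  max_step_px <- max_step_um / ps
  assoc_px <- max(8, 2 * max_step_px)

  structures <- list()  # each: centroid, tips (frame -> x,y px), junctions
  n_ambig <- 0L
  # the background/foreground mixture is stationary: one Otsu threshold
  # from the first frame serves the whole movie unless overridden
  thr <- threshold %||% otsu_threshold(movie$data[1, , ])

  # 3-frame temporal majority vote on the binary mask: pixels sitting on
  # the anti-aliased edge flip with noise frame to frame; the vote removes
  # that flicker without moving any boundary that persists
  masks <- movie$data >= thr
  if (d[1] >= 3) {
    lead <- masks[c(2:d[1], d[1]), , , drop = FALSE]
    lag <- masks[c(1, 1:(d[1] - 1)), , , drop = FALSE]
    masks <- (masks + lead + lag) >= 2
  }

  prev_mask <- NULL; prev_lab <- NULL
  for (k in seq_len(d[1])) {
    img <- movie$data[k, , ]
    mk <- masks[k, , ]
    if (!is.null(prev_mask) && identical(mk, prev_mask)) {
      lab <- prev_lab
    } else {
      lab <- label_2d(mk)
      prev_mask <- mk; prev_lab <- lab
    }
    if (!length(lab$membership)) next
    comp_ids <- unique(lab$membership)
    for (cid in comp_ids) {
      px <- lab$coords[lab$membership == cid, , drop = FALSE]
      if (nrow(px) < min_component_px) next
      # padded crop around the component
      r0 <- max(1L, min(px[, 1]) - 2L); r1 <- min(nrow(img), max(px[, 1]) + 2L)
      c0 <- max(1L, min(px[, 2]) - 2L); c1 <- min(ncol(img), max(px[, 2]) + 2L)
      crop <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
      crop[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
      centroid <- c(mean(px[, 2]), mean(px[, 1]))  # (x, y) px

      # match to an existing structure
      sid <- NA_integer_
      if (length(structures)) {
        cent_d <- vapply(structures, function(s)
          sqrt(sum((s$centroid - centroid)^2)), numeric(1))
        j <- which.min(cent_d)
        if (cent_d[j] <= assoc_px) sid <- j
      }
      if (is.na(sid)) {
        structures[[length(structures) + 1L]] <- list(
          centroid = centroid, tips = list(), junctions = list(),
          others = list())
        sid <- length(structures)
      }
      s <- structures[[sid]]

      # the binary mask is usually unchanged between consecutive frames;
      # reuse the cached skeleton / endpoints when it is
      if (!is.null(s$crop) && identical(s$crop_off, c(r0, c0)) &&
          identical(s$crop, crop)) {
        skel <- s$skel; ends <- s$ends; junc_xy <- s$junc_xy
      } else {
        skel <- zhang_suen(crop)
        nb <- neighbour_count_8(skel)
        ends <- which(skel & nb == 1, arr.ind = TRUE)
        junc <- which(skel & nb >= 3, arr.ind = TRUE)
        # median is robust to spurious junction pixels at staircase kinks
        junc_xy <- if (nrow(junc)) c(stats::median(junc[, 2]) + c0 - 1,
                                     stats::median(junc[, 1]) + r0 - 1) else NULL
        s$crop <- crop; s$crop_off <- c(r0, c0)
        s$skel <- skel; s$ends <- ends; s$junc_xy <- junc_xy
      }
      if (nrow(ends) == 0) {
        structures[[sid]] <- s
        next
      }
      epts <- cbind(ends[, 2] + c0 - 1, ends[, 1] + r0 - 1)  # (x, y) px

      # pick the tip endpoint (pixel precision suffices for the choice)
      prev <- s$tip_prev
      ti <- if (!is.null(prev)) {
        dd <- sqrt(rowSums((epts - matrix(prev, nrow(epts), 2, byrow = TRUE))^2))
        if (sum(dd <= max_step_px + 1) > 1) n_ambig <- n_ambig + 1L
        which.min(dd)
      } else if (!is.null(junc_xy)) {
        which.max(sqrt(rowSums((epts - matrix(junc_xy, nrow(epts), 2, byrow = TRUE))^2)))
      } else {
        which.max(sqrt(rowSums((epts - matrix(centroid, nrow(epts), 2, byrow = TRUE))^2)))
      }
      # sub-pixel refinement of the selected tip only
      img_c <- img[r0:r1, c0:c1, drop = FALSE]
      tip_loc <- refine_tip(img_c, skel, unname(ends[ti, ]), tip_offset_px)
      tip <- c(tip_loc[1] + c0 - 1, tip_loc[2] + r0 - 1)
      s$tips[[as.character(k)]] <- tip
      s$tip_prev <- tip
      if (!is.null(junc_xy)) s$junctions[[as.character(k)]] <- junc_xy
      if (nrow(epts) > 1) {
        s$others[[as.character(k)]] <- epts[-ti, , drop = FALSE]
      }
      s$centroid <- centroid
      structures[[sid]] <- s
    }
  }

  assemble_tracks(structures, d[1], ps, dt, min_lifetime_frames, n_ambig)
}

# Turn accumulated per-frame structure observations into tidy tracks.
assemble_tracks <- function(structures, n_frames, ps, dt, min_lifetime,
                            n_ambig) {
  keep <- Filter(function(s) length(s$tips) >= min_lifetime, structures)
  empty <- tibble(filo_id = integer(), frame = integer(), time_s = numeric(),
                  tip_x_um = numeric(), tip_y_um = numeric(),
                  length_um = numeric(), interpolated = logical())
  bases <- tibble(filo_id = integer(), base_x_um = numeric(),
                  base_y_um = numeric())
  if (!length(keep)) {
    return(structure(empty, class = c("filo_tracks", class(empty)),
                     bases = bases, n_ambiguous_links = n_ambig,
                     frame_interval_s = dt, pixel_size_um = ps))
  }

  recs <- lapply(keep, function(s) {
    frames <- sort(as.integer(names(s$tips)))
    tips <- do.call(rbind, s$tips[as.character(frames)])
    # base anchor: midpoint of the static non-tip endpoints (for a
    # perpendicular parent branch this is exactly the junction), median
    # over frames; fall back to the junction estimate, then the first tip
    base_px <- if (length(s$others)) {
      apply(do.call(rbind, lapply(s$others, colMeans)), 2, stats::median)
    } else if (length(s$junctions)) {
      apply(do.call(rbind, s$junctions), 2, stats::median)
    } else {
      tips[1, ]
    }
    full <- frames[1]:frames[length(frames)]
    xi <- stats::approx(frames, tips[, 1], xout = full)$y
    yi <- stats::approx(frames, tips[, 2], xout = full)$y
    tibble(frame = full, tip_x_px = xi, tip_y_px = yi,
           interpolated = !(full %in% frames),
           base_x_px = base_px[1], base_y_px = base_px[2])
  })
  # deterministic ids: order structures by base position
  ord <- order(vapply(recs, function(r) r$base_y_px[1], numeric(1)),
               vapply(recs, function(r) r$base_x_px[1], numeric(1)))
  out <- dplyr::bind_rows(lapply(seq_along(ord), function(i) {
    r <- recs[[ord[i]]]
    tibble(filo_id = i, frame = r$frame, time_s = (r$frame - 1) * dt,
           tip_x_um = px_to_um(r$tip_x_px, ps),
           tip_y_um = px_to_um(r$tip_y_px, ps),
           length_um = sqrt((r$tip_x_px - r$base_x_px)^2 +
                            (r$tip_y_px - r$base_y_px)^2) * ps,
           interpolated = r$interpolated)
  }))
  bases <- dplyr::bind_rows(lapply(seq_along(ord), function(i) {
    r <- recs[[ord[i]]]
    tibble(filo_id = i, base_x_um = px_to_um(r$base_x_px[1], ps),
           base_y_um = px_to_um(r$base_y_px[1], ps))
  }))
  structure(out, class = c("filo_tracks", class(out)), bases = bases,
            n_ambiguous_links = n_ambig, frame_interval_s = dt,
            pixel_size_um = ps)
}

# Build tracks from a precomputed tip table instead of a movie.
tracks_from_table <- function(tips, frame_interval_s = NULL) {
  need <- c("filo_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(tips))) {
    abort(sprintf("`tips` must have columns %s.", paste(need, collapse = ", ")))
  }
  has_time <- "time_s" %in% names(tips)
  if (!has_time && is.null(frame_interval_s)) {
    abort("`tips` needs a `time_s` column or `frame_interval_s` must be given.")
  }
  has_base <- all(c("base_x_um", "base_y_um") %in% names(tips))
  out <- tips |>
    dplyr::group_by(.data$filo_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::mutate(
      base_x = if (has_base) .data$base_x_um else dplyr::first(.data$x_um),
      base_y = if (has_base) .data$base_y_um else dplyr::first(.data$y_um)) |>
    dplyr::ungroup()
  bases <- dplyr::distinct(out, .data$filo_id, base_x_um = .data$base_x,
                           base_y_um = .data$base_y)
  res <- out |>
    dplyr::transmute(
      filo_id = .data$filo_id, frame = as.integer(.data$frame),
      time_s = if (has_time) .data$time_s else (.data$frame - 1) * frame_interval_s,
      tip_x_um = .data$x_um, tip_y_um = .data$y_um,
      length_um = sqrt((.data$x_um - .data$base_x)^2 +
                       (.data$y_um - .data$base_y)^2),
      interpolated = FALSE)
  structure(res, class = c("filo_tracks", class(res)), bases = bases,
            n_ambiguous_links = 0L,
            frame_interval_s = frame_interval_s %||% NA_real_,
            pixel_size_um = NA_real_)
}

#' Base anchor positions of tracked filopodia
#' @param tracks A `filo_tracks` tibble from [track_tips()].
#' @return Tibble with `filo_id`, `base_x_um`, `base_y_um`.
#' @export
track_bases <- function(tracks) {
  attr(tracks, "bases") %||%
    abort("`tracks` carries no base information; was it built by track_tips()?")
}
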