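# Independent brute-force oracles used to cross-check the implementation.

# Flood fill over a logical [t, y, x] volume with 4-neighbourhood in space
# and same-pixel adjacency in time. Returns a list of voxel index matrices
# (one per component), canonically sorted.
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  comps <- list()
  idx <- which(mask)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (start in idx) {
    if (seen[start]) next
    stack <- list(arrayInd(start, d)[1, ])
    seen[start] <- TRUE
    members <- list()
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      members[[length(members) + 1]] <- v
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    m <- do.call(rbind, members)
    comps[[length(comps) + 1]] <- m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
  }
  comps
}

# 26-connected flood fill over a logical volume; returns component sizes.
oracle_flood_fill_26 <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  sizes <- integer(0)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in which(mask)) {
    if (seen[start]) next
    stack <- list(arrayInd(start, d)[1, ])
    seen[start] <- TRUE
    n <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      n <- n + 1L
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && !seen[w[1], w[2], w[3]]) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    sizes <- c(sizes, n)
  }
  sizes
}

# Exhaustive minimum-total-cost one-to-one matching over candidate pairs
# (recursive branch and bound on small instances).
oracle_min_matching <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- list(value = Inf, pairs = NULL)
  recurse <- function(i, used_b, pairs, total) {
    if (i > n) {
      # maximise number of pairs first, then minimise cost
      score <- c(-nrow(pairs), total)
      bscore <- c(if (is.null(best$pairs)) 0 else -nrow(best$pairs), best$value)
      if (score[1] < bscore[1] ||
          (score[1] == bscore[1] && score[2] < bscore[2])) {
        best <<- list(value = total, pairs = pairs)
      }
      return()
    }
    recurse(i + 1, used_b, pairs, total)          # leave i unmatched
    for (j in seq_len(m)) {
      if (!used_b[j] && is.finite(cost[i, j])) {
        used_b[j] <- TRUE
        recurse(i + 1, used_b, rbind(pairs, c(i, j)), total + cost[i, j])
        used_b[j] <- FALSE
      }
    }
  }
  recurse(1, rep(FALSE, m), matrix(numeric(0), 0, 2), 0)
  best
}

# Convert a ground-truth event table (disks) into a ca_events-like tibble
# with discretized footprints, for geometry-level coupling tests.
gt_events_as_ca <- function(events, pixel_size_um, field_px) {
  fp <- lapply(seq_len(nrow(events)), function(i) {
    r <- round(events$y_um[i] / pixel_size_um) + 1
    c <- round(events$x_um[i] / pixel_size_um) + 1
    rad <- ceiling(events$radius_um[i] / pixel_size_um) + 1
    rows <- max(1, r - rad):min(field_px[1], r + rad)
    cols <- max(1, c - rad):min(field_px[2], c + rad)
    g <- expand.grid(r = rows, c = cols)
    yy <- (g$r - 1) * pixel_size_um; xx <- (g$c - 1) * pixel_size_um
    keep <- sqrt((yy - events$y_um[i])^2 + (xx - events$x_um[i])^2) <=
      events$radius_um[i]
    as.matrix(g[keep, c("r", "c")])
  })
  out <- events
  out$footprint <- fp
  structure(out, pixel_size_um = pixel_size_um, frame_interval_s = NA_real_)
}
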