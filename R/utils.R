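# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a small stream offset, kept well
# inside 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 97L + as.numeric(stream)) %% 2147483629
}

# Encode (frame, row, col) voxel coordinates as a single integer key for
# O(1) set membership via match(). dims = c(T, H, W).
voxel_key <- function(t, r, c, dims) {
  (as.numeric(t) - 1) * dims[2] * dims[3] + (as.numeric(r) - 1) * dims[3] +
    as.numeric(c)
}

pixel_key <- function(r, c, dims_hw) {
  (as.numeric(r) - 1) * dims_hw[2] + as.numeric(c)
}

# Map a physical position (um) to the 1-based index of the pixel whose
# centre is nearest (pixel centres sit at (i-1)*pixel_size_um).
um_to_px <- function(u, pixel_size_um) {
  round(u / pixel_size_um) + 1
}

px_to_um <- function(i, pixel_size_um) {
  (i - 1) * pixel_size_um
}

# Connected components of a sparse voxel set given an offset stencil.
# `coords` is a matrix with one row per voxel; `offsets` one row per
# (half-)neighbourhood offset. Returns an integer membership vector.
sparse_components <- function(coords, offsets, dims) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  keys <- voxel_key(coords[, 1], coords[, 2], coords[, 3], dims)
  ord <- order(keys)
  keys_sorted <- keys[ord]
  edges <- vector("list", nrow(offsets))
  for (j in seq_len(nrow(offsets))) {
    t2 <- coords[, 1] + offsets[j, 1]
    r2 <- coords[, 2] + offsets[j, 2]
    c2 <- coords[, 3] + offsets[j, 3]
    ok <- t2 >= 1 & t2 <= dims[1] & r2 >= 1 & r2 <= dims[2] &
      c2 >= 1 & c2 <= dims[3]
    if (!any(ok)) next
    nb <- findInterval(voxel_key(t2[ok], r2[ok], c2[ok], dims), keys_sorted)
    hit <- nb > 0 & keys_sorted[pmax(nb, 1)] ==
      voxel_key(t2[ok], r2[ok], c2[ok], dims)
    if (!any(hit)) next
    from <- which(ok)[hit]
    to <- ord[nb[hit]]
    edges[[j]] <- cbind(from, to)
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::components(g)$membership
}

# Offset stencils (forward half-neighbourhoods; symmetry is implied by the
# undirected graph). Space: 4-neighbourhood; time: same-pixel adjacency.
stencil_spatiotemporal <- function() {
  rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
}

# Full 26-connectivity in 3D (13 forward offsets).
stencil_26 <- function() {
  out <- expand.grid(t = -1:1, r = -1:1, c = -1:1)
  out <- as.matrix(out[out$t > 0 | (out$t == 0 & (out$r > 0 | (out$r == 0 & out$c > 0))), ])
  unname(out)
}

# Mean +/- SEM of a numeric vector, NA-safe.
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(mean = if (n) mean(x) else NA_real_,
       sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}

`%||%` <- rlang::`%||%`
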