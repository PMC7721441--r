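#' Movie stack container
#'
#' A `movie_stack` holds one imaging channel of a time-lapse recording as a
#' `[frame, row, col]` numeric array together with its physical calibration.
#' Frame `k` (1-based) is at time `(k - 1) * frame_interval_s` seconds and
#' pixel `(r, c)` has its centre at `((c-1), (r-1)) * pixel_size_um`
#' micrometres.
#'
#' @param data Numeric array `[frames, height, width]` of raw fluorescence
#'   intensities (arbitrary units, finite, non-negative).
#' @param frame_interval_s Frame interval in seconds.
#' @param pixel_size_um Pixel size in micrometres per pixel.
#' @param channel Channel label, e.g. `"ca"` or `"trachea"`.
#' @return An object of class `movie_stack`.
#' @examples
#' m <- movie_stack(array(100, c(4, 8, 8)), 0.3, 1/3, "ca")
#' dim(m$data)
#' @export
movie_stack <- function(data, frame_interval_s, pixel_size_um,
                        channel = "ca") {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3D array [frames, height, width].")
  }
  if (dim(data)[1] < 2) abort("movie must have at least 2 frames.")
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    abort("intensities must be finite and non-negative.")
  }
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    abort("`frame_interval_s` must be a positive number.")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a positive number.")
  }
  structure(
    list(data = data, frame_interval_s = frame_interval_s,
         pixel_size_um = pixel_size_um, channel = as.character(channel)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<movie_stack> channel '%s': %d frames of %d x %d px (%.3g s/frame, %.3g um/px)\n",
    x$channel, d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' Frame times of a movie stack
#' @param movie A [movie_stack()].
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - 1) * movie$frame_interval_s
}

#' Read a multi-page grayscale TIFF into a movie stack
#'
#' @param path Path to a multi-page TIFF (one page per frame).
#' @inheritParams movie_stack
#' @param scale Intensity scale applied to the `[0, 1]` values returned by
#'   the TIFF reader; the default restores 16-bit integer units.
#' @return A [movie_stack()].
#' @export
read_movie_tiff <- function(path, frame_interval_s, pixel_size_um,
                            channel = "ca", scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse grayscale-as-RGB
    p * scale
  })
  arr <- array(0, c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (k in seq_along(mats)) arr[k, , ] <- mats[[k]]
  movie_stack(round(arr), frame_interval_s, pixel_size_um, channel)
}

#' Write a movie stack to a multi-page 16-bit grayscale TIFF
#'
#' @param movie A [movie_stack()].
#' @param path Output file path.
#' @param scale Full-scale intensity mapped to the TIFF maximum.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = 65535) {
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    pmin(pmax(movie$data[k, , ] / scale, 0), 1)
  })
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16), silent = TRUE)
  if (inherits(ok, "try-error")) {
    abort(sprintf("could not write TIFF to '%s'.", path))
  }
  invisible(path)
}

#' Maximum-intensity projection over time
#'
#' Collapses a movie to a single `height x width` matrix of per-pixel
#' temporal maxima, the standard display for showing every transient of a
#' recording in one image.
#'
#' @param movie A [movie_stack()].
#' @return Numeric matrix `[height, width]`.
#' @export
max_projection <- function(movie) {
  apply(movie$data, c(2, 3), max)
}
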