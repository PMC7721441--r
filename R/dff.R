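#' Compute dF/F0 from a raw movie
#'
#' Converts raw fluorescence `F_t` into the fractional change
#' `(F_t - F0) / F0` per pixel. The baseline `F0` is either the per-pixel
#' temporal percentile (default: 20th, robust to sparse transients) or a
#' single global constant. Pixels whose baseline does not exceed `epsilon`
#' are masked and excluded from all downstream analysis.
#'
#' @param movie A [movie_stack()].
#' @param baseline_method `"percentile"` (per-pixel temporal percentile) or
#'   `"global"` (one constant for the whole movie).
#' @param percentile Percentile in `[0, 100]` used when
#'   `baseline_method = "percentile"`.
#' @param f0 Baseline constant used when `baseline_method = "global"`; when
#'   `NULL` it defaults to the `percentile` of all intensities.
#' @param epsilon Baselines at or below this value are masked.
#' @return An object of class `dff_movie`: list with `dff` (T x H x W array
#'   of dF/F0 fractions, `NA` at masked pixels), `f0_map`, `mask` (TRUE =
#'   valid), `baseline_method`, and the movie calibration.
#' @examples
#' m <- movie_stack(array(100, c(4, 4, 4)), 0.3, 1/3)
#' d <- compute_dff(m)
#' range(d$dff)
#' @export
compute_dff <- function(movie, baseline_method = c("percentile", "global"),
                        percentile = 20, f0 = NULL, epsilon = 1e-6) {
  baseline_method <- match.arg(baseline_method)
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  if (all(movie$data == 0)) abort("no valid baseline: movie is all zero.")

  f0_map <- if (baseline_method == "percentile") {
    apply(movie$data, c(2, 3), quantile, probs = percentile / 100, names = FALSE)
  } else {
    matrix(f0 %||% quantile(movie$data, percentile / 100, names = FALSE),
           d[2], d[3])
  }
  mask <- f0_map > epsilon
  if (!any(mask)) abort("no valid baseline: every pixel is masked.")
  n_masked <- sum(!mask)
  if (n_masked > 0) {
    inform(sprintf("%d pixel(s) masked (baseline <= %g).", n_masked, epsilon))
  }

  f0_safe <- ifelse(mask, f0_map, NA_real_)
  dff <- sweep(movie$data, c(2, 3), f0_safe, "-")
  dff <- sweep(dff, c(2, 3), f0_safe, "/")
  structure(
    list(dff = dff, f0_map = f0_map, mask = mask,
         baseline_method = sprintf(
           "%s%s", baseline_method,
           if (baseline_method == "percentile") sprintf(" p%g", percentile) else ""),
         frame_interval_s = movie$frame_interval_s,
         pixel_size_um = movie$pixel_size_um),
    class = "dff_movie")
}

#' @export
print.dff_movie <- function(x, ...) {
  d <- dim(x$dff)
  cat(sprintf("<dff_movie> %d frames of %d x %d px, baseline %s, %d masked px\n",
              d[1], d[2], d[3], x$baseline_method, sum(!x$mask)))
  invisible(x)
}
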