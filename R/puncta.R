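#' Count fluorescent puncta in a z-stack
#'
#' Threshold-and-label segmentation for punctate staining (e.g. oxidized
#' ROS-indicator puncta): voxels at or above `intensity_threshold` are
#' grouped into 26-connected 3D components, and components with at least
#' `min_voxels` voxels are counted as puncta.
#'
#' @param zstack Numeric 3D array `[z, y, x]`.
#' @param intensity_threshold Inclusive intensity threshold.
#' @param min_voxels Minimum component size in voxels.
#' @return A list: `n_puncta` and a `puncta` tibble with per-punctum voxel
#'   count and centroid (pixel units).
#' @export
count_puncta <- function(zstack, intensity_threshold, min_voxels = 1) {
  if (!is.array(zstack) || length(dim(zstack)) != 3 || length(zstack) == 0) {
    abort("`zstack` must be a non-empty 3D array.")
  }
  d <- dim(zstack)
  idx <- which(zstack >= intensity_threshold)
  if (length(idx) == 0) {
    return(list(n_puncta = 0L,
                puncta = tibble(punctum_id = integer(), n_voxels = integer(),
                                z = numeric(), y = numeric(), x = numeric())))
  }
  co <- arrayInd(idx, d)
  memb <- sparse_components(co, stencil_26(), d)
  puncta <- tibble(z = co[, 1], y = co[, 2], x = co[, 3], memb = memb) |>
    dplyr::summarise(n_voxels = dplyr::n(), z = mean(.data$z),
                     y = mean(.data$y), x = mean(.data$x), .by = "memb") |>
    dplyr::filter(.data$n_voxels >= min_voxels) |>
    dplyr::arrange(dplyr::desc(.data$n_voxels)) |>
    dplyr::mutate(punctum_id = dplyr::row_number(), memb = NULL) |>
    dplyr::relocate("punctum_id")
  list(n_puncta = nrow(puncta), puncta = puncta)
}
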