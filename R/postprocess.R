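#' Threshold a probability heatmap into a binary mask
#'
#' A voxel becomes positive when its probability is greater than or equal to
#' the threshold (boundary inclusive).
#'
#' @param hm a [heatmap_volume()].
#' @param threshold decision threshold in (0, 1).
#' @return A [mask_volume()].
#' @export
binarize <- function(hm, threshold = 0.5) {
  stopifnot(inherits(hm, "heatmap"), threshold > 0, threshold < 1)
  mask_volume((hm$probabilities >= threshold) * 1L)
}

#' Label connected components of a binary mask
#'
#' 3D connected components under 6-, 18- or 26-connectivity, or per-slice 2D
#' components (`mode = "2d"`, where 6 maps to 4-connectivity and 18/26 to
#' 8-connectivity).
#'
#' @param mask a [mask_volume()] or 3D 0/1 array.
#' @param connectivity 6, 18 or 26.
#' @param mode `"3d"` (default) or `"2d"`.
#' @return Integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26L, mode = c("3d", "2d")) {
  mode <- match.arg(mode)
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  arr <- if (inherits(mask, "mask_volume")) mask$labels else mask
  storage.mode(arr) <- "integer"
  label_components_cpp(arr, as.integer(connectivity), mode == "2d")
}

#' Remove connected components smaller than a voxel-count threshold
#'
#' Components with strictly fewer than `min_voxels` voxels are erased;
#' components with `min_voxels` or more survive untouched. The default of
#' 50 voxels with 26-connectivity in 3D matches the deployed pipeline.
#'
#' @param mask a [mask_volume()].
#' @param min_voxels minimum surviving component size (>= 1).
#' @param connectivity 6, 18 or 26.
#' @param mode `"3d"` component analysis (default) or per-slice `"2d"`.
#' @return A [mask_volume()]; never adds a positive voxel.
#' @export
remove_small_clusters <- function(mask, min_voxels = 50L, connectivity = 26L,
                                  mode = "3d") {
  stopifnot(inherits(mask, "mask_volume"), min_voxels >= 1)
  lab <- label_components(mask, connectivity, mode)
  if (max(lab) == 0L) return(mask_volume(array(0L, dim = dim(mask$labels))))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  out <- array(0L, dim = dim(lab))
  out[lab %in% keep] <- 1L
  mask_volume(out)
}

#' Smooth mask boundaries with a per-slice binary median filter
#'
#' Each slice is filtered with an odd square window (zero padding at the
#' image border); the output voxel is the median of the binary values in the
#' window, i.e. the majority vote. Isolated voxels disappear, ragged edges
#' and corners are rounded, and large solid regions are preserved.
#'
#' @param mask a [mask_volume()].
#' @param window odd window size >= 3.
#' @return A [mask_volume()].
#' @export
smooth_boundaries <- function(mask, window = 3L) {
  stopifnot(inherits(mask, "mask_volume"))
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  arr <- mask$labels
  storage.mode(arr) <- "integer"
  mask_volume(median_filter_slices_cpp(arr, as.integer(window)))
}

#' Full postprocessing: threshold, cluster removal, boundary smoothing
#'
#' Applies [binarize()], [remove_small_clusters()] and [smooth_boundaries()]
#' in that order. Smoothing runs last, so a surviving component may end
#' slightly below the cluster threshold after smoothing; no re-filtering is
#' applied.
#'
#' @param hm a [heatmap_volume()].
#' @param cfg a `run_config`; consulted fields: `threshold`,
#'   `cluster_min_voxels`, `connectivity`, `median_window`.
#' @return A [mask_volume()].
#' @export
postprocess_heatmap <- function(hm, cfg = default_config("desk")) {
  m <- binarize(hm, cfg$threshold)
  m <- remove_small_clusters(m, cfg$cluster_min_voxels, cfg$connectivity)
  smooth_boundaries(m, cfg$median_window)
}
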