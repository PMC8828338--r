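#' Per-slice white top-hat transform
#'
#' Subtracts the morphological opening (disc structuring element) from each
#' slice, extracting bright structures smaller than the disc and flattening
#' the smooth background. Output is non-negative and never exceeds the input
#' (anti-extensivity of the opening).
#'
#' @param vol an [image_volume()].
#' @param radius_px disc radius in pixels (>= 1); must be smaller than half
#'   the slice extent.
#' @return An [image_volume()] of top-hat responses.
#' @export
white_top_hat <- function(vol, radius_px = 50L) {
  stopifnot(inherits(vol, "image_volume"), radius_px >= 1)
  d <- dim(vol$voxels)
  size <- 2L * as.integer(radius_px) + 1L
  if (size > min(d[2L], d[3L])) {
    stop(sprintf("structuring element (%d px) exceeds slice extent (%d x %d)",
                 size, d[2L], d[3L]))
  }
  brush <- EBImage::makeBrush(size, shape = "disc")
  out <- vol$voxels
  for (s in seq_len(d[1L])) {
    out[s, , ] <- EBImage::whiteTopHat(vol$voxels[s, , ], brush)
  }
  out[out < 0] <- 0
  image_volume(out, vol$pixel_spacing_mm, vol$slice_spacing_mm)
}

#' Detect candidate mass centres on a top-hat response volume
#'
#' Per-slice local maxima of the response above a per-volume percentile
#' threshold, thinned so that within a slice no two candidates are closer
#' than `min_separation_px` (the higher response wins a conflict).
#'
#' @param tophat an [image_volume()] of top-hat responses.
#' @param percentile per-volume response percentile (in (50, 100)) below which
#'   maxima are discarded.
#' @param min_separation_px minimum in-plane separation between retained
#'   candidates within a slice.
#' @return `data.frame(slice, row, col, response)`; zero rows when nothing
#'   exceeds the threshold.
#' @export
detect_candidates <- function(tophat, percentile = 99.5, min_separation_px = 100) {
  stopifnot(inherits(tophat, "image_volume"),
            percentile > 50, percentile < 100, min_separation_px >= 1)
  vox <- tophat$voxels
  if (max(vox) <= 0) {
    return(data.frame(slice = integer(), row = integer(), col = integer(),
                      response = numeric()))
  }
  thresh <- quantile(vox, percentile / 100, names = FALSE)
  d <- dim(vox)
  # max filter via grayscale dilation over a disc of the separation radius
  size <- 2L * as.integer(ceiling(min_separation_px / 2)) + 1L
  size <- min(size, 2L * (min(d[2L], d[3L]) %/% 2L) - 1L)
  brush <- EBImage::makeBrush(max(size, 3L), shape = "disc")
  out <- list()
  for (s in seq_len(d[1L])) {
    sl <- vox[s, , ]
    mx <- EBImage::dilate(sl, brush)
    idx <- which(sl >= mx & sl > thresh & sl > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    resp <- sl[idx]
    ord <- order(resp, decreasing = TRUE)
    kept <- matrix(numeric(0), ncol = 2L)
    kresp <- numeric(0)
    for (i in ord) {
      p <- idx[i, ]
      if (nrow(kept) > 0L) {
        dd <- sqrt((kept[, 1L] - p[1L])^2 + (kept[, 2L] - p[2L])^2)
        if (any(dd < min_separation_px)) next
      }
      kept <- rbind(kept, p)
      kresp <- c(kresp, resp[i])
    }
    out[[length(out) + 1L]] <- data.frame(slice = s, row = kept[, 1L],
                                          col = kept[, 2L], response = kresp)
  }
  if (!length(out)) {
    return(data.frame(slice = integer(), row = integer(), col = integer(),
                      response = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gaussian radial-basis constraint matrix
#'
#' For every slice, `M(p) = max_c exp(-||p - c||^2 / (2 sigma^2))` over the
#' candidates `c` of that slice, with `sigma = delta_mm / pixel_spacing_mm`
#' pixels (the radial basis function has variance delta^2 in mm). Slices with
#' no candidate are filled with `floor` (1 = pass-through).
#'
#' @param shape integer `(slices, rows, cols)`.
#' @param candidates data.frame from [detect_candidates()].
#' @param delta_mm RBF scale in mm (> 0); the method's default is 5 mm.
#' @param pixel_spacing_mm in-plane pixel pitch (> 0).
#' @param floor value assigned to slices without candidates, in (0, 1].
#' @return An [image_volume()] with values in (0, 1].
#' @export
constraint_matrix <- function(shape, candidates, delta_mm = 5,
                              pixel_spacing_mm = 0.1, floor = 1.0) {
  stopifnot(delta_mm > 0, pixel_spacing_mm > 0, floor > 0, floor <= 1)
  shape <- as.integer(shape)
  sigma_px <- delta_mm / pixel_spacing_mm
  M <- array(floor, dim = shape)
  if (nrow(candidates) > 0L) {
    rows <- seq_len(shape[2L])
    cols <- seq_len(shape[3L])
    for (s in unique(candidates$slice)) {
      cand <- candidates[candidates$slice == s, , drop = FALSE]
      d2min <- NULL
      for (i in seq_len(nrow(cand))) {
        d2 <- outer((rows - cand$row[i])^2, (cols - cand$col[i])^2, `+`)
        d2min <- if (is.null(d2min)) d2 else pmin(d2min, d2)
      }
      M[s, , ] <- exp(-d2min / (2 * sigma_px^2))
    }
  }
  image_volume(M, pixel_spacing_mm, 1.0)
}

#' Normalize a volume to [0, 1] by its maximum
#' @param vol an [image_volume()].
#' @return An [image_volume()].
#' @export
normalize_volume <- function(vol) {
  v <- vol$voxels
  if (max(v) > 0) v <- v / max(v)
  image_volume(v, vol$pixel_spacing_mm, vol$slice_spacing_mm)
}

#' Full preprocessing of a volume
#'
#' Normalizes the volume, adds the white top-hat response (contrast
#' enhancement), rescales to `[0, 1]`, and multiplies by the RBF constraint
#' matrix built from candidates detected on the top-hat response. Either step
#' can be disabled through the configuration; with both disabled this is the
#' identity on the normalized volume.
#'
#' @param vol an [image_volume()].
#' @param cfg a `run_config` (see [default_config()]); only the preprocessing
#'   fields are consulted.
#' @return An [image_volume()] with intensities in `[0, 1]`, same shape and
#'   metadata as the input.
#' @export
preprocess_volume <- function(vol, cfg = default_config("desk")) {
  stopifnot(inherits(vol, "image_volume"))
  out <- if (isTRUE(cfg$normalize)) normalize_volume(vol) else vol
  if (isTRUE(cfg$enable_tophat)) {
    th <- white_top_hat(out, cfg$tophat_radius_px)
    enhanced <- out$voxels + th$voxels
    if (max(enhanced) > 0) enhanced <- enhanced / max(enhanced)
    out <- image_volume(enhanced, vol$pixel_spacing_mm, vol$slice_spacing_mm)
  } else {
    th <- NULL
  }
  if (isTRUE(cfg$enable_constraint)) {
    if (is.null(th)) th <- white_top_hat(out, cfg$tophat_radius_px)
    cand <- detect_candidates(th, cfg$candidate_percentile,
                              cfg$candidate_min_separation_px)
    M <- constraint_matrix(dim(out$voxels), cand, cfg$delta_mm,
                           vol$pixel_spacing_mm, cfg$constraint_floor)
    out <- image_volume(out$voxels * M$voxels,
                        vol$pixel_spacing_mm, vol$slice_spacing_mm)
  }
  out
}
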