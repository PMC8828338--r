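#' Image volume container
#'
#' An `image_volume` is a stack of 2D grayscale slices stored as a 3D array
#' indexed `(slice, row, col)`, together with its spatial calibration: the
#' in-plane pixel pitch and the spacing between reconstructed slices, both in
#' millimetres. All indexing in the package is 1-based and window ranges are
#' inclusive of their first index, exclusive after `origin + size - 1`.
#'
#' @param voxels 3D numeric array `(slice, row, col)` of finite, non-negative
#'   intensities.
#' @param pixel_spacing_mm in-plane millimetres per pixel (> 0).
#' @param slice_spacing_mm millimetres between adjacent slices (> 0).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, pixel_spacing_mm = 0.1, slice_spacing_mm = 1.0) {
  if (length(dim(voxels)) == 2L) {
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  }
  if (length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D (slice, row, col) array")
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    bad <- which(!is.finite(voxels), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite voxel at (slice, row, col) = (%d, %d, %d)",
                 bad[1L], bad[2L], bad[3L]))
  }
  if (any(voxels < 0)) stop("voxel intensities must be >= 0")
  if (!is.numeric(pixel_spacing_mm) || pixel_spacing_mm <= 0) {
    stop("pixel_spacing_mm must be > 0")
  }
  if (!is.numeric(slice_spacing_mm) || slice_spacing_mm <= 0) {
    stop("slice_spacing_mm must be > 0")
  }
  structure(list(voxels = voxels,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_spacing_mm = as.numeric(slice_spacing_mm)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %d slice(s) of %d x %d, %.4g mm/px, %.4g mm/slice\n",
              d[1L], d[2L], d[3L], x$pixel_spacing_mm, x$slice_spacing_mm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Binary mask volume, optionally with per-lesion instance labels
#'
#' @param labels 3D array of 0/1 voxel labels aligned to an [image_volume()].
#' @param lesion_ids optional 3D integer array; 0 marks background and each
#'   positive integer one lesion instance. Must be positive exactly where
#'   `labels == 1`.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(labels, lesion_ids = NULL) {
  if (length(dim(labels)) == 2L) labels <- array(labels, dim = c(1L, dim(labels)))
  if (length(dim(labels)) != 3L) stop("labels must be a 3D (slice, row, col) array")
  if (!all(labels %in% c(0, 1))) stop("mask labels must be 0 or 1")
  storage.mode(labels) <- "integer"
  if (!is.null(lesion_ids)) {
    if (!identical(dim(lesion_ids), dim(labels))) {
      stop("lesion_ids must have the same shape as labels")
    }
    storage.mode(lesion_ids) <- "integer"
    if (any(lesion_ids < 0)) stop("lesion_ids must be >= 0")
    if (!identical(unname(lesion_ids > 0L), unname(labels == 1L))) {
      stop("lesion_ids must be positive exactly where labels == 1")
    }
  }
  structure(list(labels = labels, lesion_ids = lesion_ids),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$labels)
  nl <- if (is.null(x$lesion_ids)) NA_integer_ else length(setdiff(unique(as.vector(x$lesion_ids)), 0L))
  cat(sprintf("<mask_volume> %d x %d x %d, %d positive voxel(s), %s lesion(s)\n",
              d[1L], d[2L], d[3L], sum(x$labels),
              ifelse(is.na(nl), "untracked", as.character(nl))))
  invisible(x)
}

#' Read a multi-page TIFF stack as an image volume
#'
#' Each TIFF page becomes one slice. Pages must be single-channel and share
#' identical dimensions. Integer-typed TIFF data are returned on their native
#' integer scale (so a write/read round trip is bit-exact); set
#' `normalize = TRUE` to rescale by the per-volume maximum to `[0, 1]` at load
#' time instead (the preprocessing stage otherwise normalizes on entry).
#'
#' @param path path to an existing multi-page grayscale TIFF.
#' @param pixel_spacing_mm,slice_spacing_mm spatial calibration to attach; TIFF
#'   tags are not consulted.
#' @param normalize if `TRUE`, divide by the per-volume maximum after reading.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, pixel_spacing_mm = 0.1, slice_spacing_mm = 1.0,
                        normalize = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) > 2L && dim(pages[[i]])[3L] > 1L) {
      stop(sprintf("page %d has %d channels; expected single-channel grayscale",
                   i, dim(pages[[i]])[3L]))
    }
    # 8/16-bit pages hold integers (returned scaled to [0, 1]; restore the
    # native scale); 32-bit pages hold float samples and pass through
    bits <- attr(pages[[i]], "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    if (bits < 32L) {
      pages[[i]] <- round(pages[[i]] * (2^bits - 1))
    }
    pages[[i]] <- pages[[i]][, , drop = TRUE]
    if (!identical(dim(pages[[i]]), dim(pages[[1L]]))) {
      stop(sprintf("page %d dimensions (%s) differ from page 1 (%s)",
                   i, paste(dim(pages[[i]]), collapse = "x"),
                   paste(dim(pages[[1L]]), collapse = "x")))
    }
  }
  d <- dim(pages[[1L]])
  vox <- array(0, dim = c(length(pages), d[1L], d[2L]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  if (normalize && max(vox) > 0) vox <- vox / max(vox)
  image_volume(vox, pixel_spacing_mm, slice_spacing_mm)
}

#' Read a multi-page TIFF as a binary mask volume
#'
#' Non-zero pixels become 1. Lesion instance labels are not stored in TIFF;
#' re-derive them with [label_components()] if needed.
#'
#' @inheritParams read_volume
#' @return A [mask_volume()].
#' @export
read_mask <- function(path) {
  vol <- read_volume(path, normalize = FALSE)
  mask_volume((vol$voxels > 0) * 1L)
}

#' Write an image or mask volume as a multi-page TIFF
#'
#' Masks are written as 8-bit pages holding the literal values 0 and 1.
#' Integer-valued images within `[0, 65535]` are written as 16-bit pages
#' (bit-exact round trip through [read_volume()]); anything else is written as
#' 32-bit float.
#'
#' @param vol an [image_volume()] or [mask_volume()].
#' @param path output file path; the parent directory must exist.
#' @param type `"auto"`, `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, type = c("auto", "uint8", "uint16", "float32")) {
  type <- match.arg(type)
  if (inherits(vol, "mask_volume")) {
    vox <- vol$labels
    if (type == "auto") type <- "uint8"
  } else if (inherits(vol, "image_volume")) {
    vox <- vol$voxels
  } else {
    stop("vol must be an image_volume or mask_volume")
  }
  if (anyNA(vox) || any(!is.finite(vox))) {
    bad <- which(!is.finite(vox), arr.ind = TRUE)[1L, ]
    stop(sprintf("refusing to write non-finite voxel at (slice, row, col) = (%d, %d, %d)",
                 bad[1L], bad[2L], bad[3L]))
  }
  if (!dir.exists(dirname(path))) stop(sprintf("directory not writable: %s", dirname(path)))
  if (type == "auto") {
    intish <- all(vox == round(vox))
    type <- if (intish && max(vox) <= 65535 && min(vox) >= 0) "uint16" else "float32"
  }
  n_slices <- dim(vox)[1L]
  pages <- vector("list", n_slices)
  for (s in seq_len(n_slices)) {
    sl <- vox[s, , ]
    pages[[s]] <- switch(type,
      uint8 = sl / 255,
      uint16 = sl / 65535,
      float32 = sl)
  }
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float32 = 32L)
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

# ---- run configuration -------------------------------------------------------

config_schema <- function() {
  list(
    seed = list(default = 42L, check = function(x) is.numeric(x) && x == round(x)),
    pixel_spacing_mm = list(default = 0.1, check = function(x) is.numeric(x) && x > 0),
    slice_spacing_mm = list(default = 1.0, check = function(x) is.numeric(x) && x > 0),
    normalize = list(default = TRUE, check = is.logical),
    # preprocessing
    tophat_radius_px = list(default = 50L, check = function(x) x >= 1 && x == round(x)),
    delta_mm = list(default = 5, check = function(x) is.numeric(x) && x > 0),
    candidate_percentile = list(default = 99.5, check = function(x) x > 50 && x < 100),
    candidate_min_separation_px = list(default = 100, check = function(x) x >= 1),
    constraint_floor = list(default = 1.0, check = function(x) x > 0 && x <= 1),
    enable_tophat = list(default = TRUE, check = is.logical),
    enable_constraint = list(default = TRUE, check = is.logical),
    # patching
    patch_size = list(default = 256L, check = function(x) x >= 1 && x == round(x)),
    stride = list(default = 28L, check = function(x) x >= 1 && x == round(x)),
    per_class_n = list(default = 18750L, check = function(x) x >= 1 && x == round(x)),
    augment = list(default = TRUE, check = is.logical),
    # architecture
    channels = list(default = 32L, check = function(x) x >= 1 && x == round(x)),
    # training
    batch_size = list(default = 150L, check = function(x) x >= 1 && x == round(x)),
    epochs = list(default = 1000L, check = function(x) x >= 1 && x == round(x)),
    learning_rate = list(default = 0.01, check = function(x) x > 0),
    alpha = list(default = 1, check = function(x) x > 0),
    loss_epsilon = list(default = 1e-6, check = function(x) x >= 0),
    # postprocessing
    threshold = list(default = 0.5, check = function(x) x > 0 && x < 1),
    cluster_min_voxels = list(default = 50L, check = function(x) x >= 1 && x == round(x)),
    connectivity = list(default = 26L, check = function(x) x %in% c(6, 18, 26)),
    median_window = list(default = 3L, check = function(x) x >= 3 && x %% 2 == 1),
    # evaluation
    match_rule = list(default = "any_overlap",
                      check = function(x) x %in% c("any_overlap", "centroid", "fraction"))
  )
}

#' Default run configuration
#'
#' Returns the full parameter set of the pipeline as a named list. The
#' `"paper"` profile carries the full-scale settings (patch 256, stride 28,
#' batch 150, 1000 epochs, top-hat radius 50 px); the `"desk"` profile is a
#' scaled-down configuration for CPU-sized experiments (patch 64, stride 16,
#' batch 16, 20 epochs) with the same method parameters (`alpha = 1`,
#' `delta_mm = 5`, `cluster_min_voxels = 50`, `learning_rate = 0.01`).
#'
#' @param profile `"paper"` or `"desk"`.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(profile = c("paper", "desk")) {
  profile <- match.arg(profile)
  cfg <- lapply(config_schema(), `[[`, "default")
  if (profile == "desk") {
    cfg <- modifyList(cfg, list(
      patch_size = 64L, stride = 16L, per_class_n = 12L,
      batch_size = 16L, epochs = 20L,
      tophat_radius_px = 30L,
      candidate_percentile = 99.0,
      candidate_min_separation_px = 25
    ))
  }
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (!isTRUE(schema[[key]]$check(val))) {
      stop(sprintf("config value out of range for '%s': %s", key,
                   paste(format(val), collapse = ", ")))
    }
  }
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file take their documented defaults; unknown keys and
#' out-of-range values are rejected with the offending field name. An empty
#' (or `NULL`) path yields the default configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param profile base profile supplying defaults, see [default_config()].
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL, profile = "paper") {
  cfg <- unclass(default_config(profile))
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (length(user)) {
      validate_config(user)
      for (key in names(user)) {
        tmpl <- cfg[[key]]
        val <- user[[key]]
        if (is.integer(tmpl)) {
          val <- as.integer(val)
        } else if (is.double(tmpl)) {
          val <- as.double(val)
        }
        cfg[[key]] <- val
      }
    }
  }
  cfg <- structure(cfg, class = "run_config")
  validate_config(cfg)
  cfg
}

#' Save a run configuration to a YAML file
#'
#' `load_config(save_config(cfg, p))` reproduces `cfg` exactly.
#'
#' @param cfg a `run_config` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  validate_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
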