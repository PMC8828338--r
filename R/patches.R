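#' Enumerate sliding-window patch origins
#'
#' Origins are the 1-based top-left corners `1 + i * stride` (row) and
#' `1 + j * stride` (col) for all non-negative `i`, `j` such that the
#' `patch_size`-wide window stays inside the slice. The count is
#' `(floor((H - P) / s) + 1) * (floor((W - P) / s) + 1)`.
#'
#' @param height,width slice dimensions.
#' @param patch_size window side length (<= both dimensions).
#' @param stride step between adjacent origins (1 <= stride).
#' @return Integer matrix with columns `row`, `col`, in row-major order.
#' @export
enumerate_origins <- function(height, width, patch_size, stride) {
  stopifnot(patch_size >= 1, stride >= 1)
  if (patch_size > min(height, width)) {
    stop(sprintf("patch size %d exceeds slice extent %d x %d",
                 patch_size, height, width))
  }
  rows <- seq.int(1L, height - patch_size + 1L, by = stride)
  cols <- seq.int(1L, width - patch_size + 1L, by = stride)
  out <- cbind(row = rep(rows, each = length(cols)),
               col = rep(cols, times = length(rows)))
  storage.mode(out) <- "integer"
  out
}

new_patch <- function(pixels, slice, origin, label, rotation = 0L) {
  structure(list(pixels = pixels, slice = as.integer(slice),
                 origin = as.integer(origin), label = as.integer(label),
                 rotation = as.integer(rotation)),
            class = "dbt_patch")
}

#' @export
print.dbt_patch <- function(x, ...) {
  cat(sprintf("<dbt_patch> %d x %d at slice %d origin (%d, %d), label %s, rot %d\n",
              nrow(x$pixels), ncol(x$pixels), x$slice, x$origin[1L], x$origin[2L],
              ifelse(x$label == 1L, "positive", "negative"), x$rotation))
  invisible(x)
}

# centre-pixel offset of a patch: floor(P / 2) from the origin
patch_center_offset <- function(patch_size) patch_size %/% 2L

#' Extract all sliding-window patches from a volume
#'
#' One patch per (slice, origin). A patch is labelled positive when the mask
#' is 1 at its central pixel (`origin + floor(P / 2)` on each in-plane axis);
#' all other patches are negative, including those far from any mass.
#'
#' @param vol an [image_volume()] (typically already preprocessed).
#' @param mask the aligned [mask_volume()].
#' @param patch_size,stride sliding-window geometry.
#' @return List of `dbt_patch` objects.
#' @export
extract_patches <- function(vol, mask, patch_size = 64L, stride = 16L) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "mask_volume"))
  if (!identical(dim(vol$voxels), dim(mask$labels))) {
    stop("volume and mask shapes differ")
  }
  d <- dim(vol$voxels)
  origins <- enumerate_origins(d[2L], d[3L], patch_size, stride)
  off <- patch_center_offset(patch_size)
  out <- vector("list", d[1L] * nrow(origins))
  n <- 0L
  for (s in seq_len(d[1L])) {
    sl <- vol$voxels[s, , ]
    ml <- mask$labels[s, , ]
    for (i in seq_len(nrow(origins))) {
      r0 <- origins[i, 1L]
      c0 <- origins[i, 2L]
      label <- ml[r0 + off, c0 + off]
      n <- n + 1L
      out[[n]] <- new_patch(sl[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)],
                            s, c(r0, c0), label)
    }
  }
  out
}

#' Class-balanced per-epoch patch sample
#'
#' Draws exactly `per_class_n` positive and `per_class_n` negative patches,
#' with replacement whenever a class holds fewer than `per_class_n` members.
#' Deterministic under `seed`.
#'
#' @param patches list of `dbt_patch`.
#' @param per_class_n draw size per class (>= 1).
#' @param seed integer seed.
#' @return List of `2 * per_class_n` patches (positives first).
#' @export
balanced_epoch_sample <- function(patches, per_class_n, seed = 1L) {
  stopifnot(per_class_n >= 1)
  labels <- vapply(patches, `[[`, integer(1L), "label")
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (!length(pos)) stop("no positive patches available for balanced sampling")
  if (!length(neg)) stop("no negative patches available for balanced sampling")
  set.seed(seed)
  take <- function(idx) sample(idx, per_class_n, replace = length(idx) < per_class_n)
  patches[c(take(pos), take(neg))]
}

# rotate a square matrix 90 degrees: out[r, c] = in[c, P + 1 - r]
rotate90 <- function(m) t(m[, ncol(m):1L, drop = FALSE])

#' Right-angle rotation augmentation of a patch
#'
#' Returns the four rotations (0, 90, 180, 270 degrees) of a square patch.
#' Labels and origins are preserved; only the pixel array and the rotation
#' tag change. Note that for even patch sizes the `floor(P / 2)` centre pixel
#' is not the fixed point of the rotation, so the label is carried over from
#' the unrotated patch rather than re-read.
#'
#' @param patch a `dbt_patch` with square pixels.
#' @return List of 4 patches.
#' @export
augment_rotations <- function(patch) {
  px <- patch$pixels
  if (nrow(px) != ncol(px)) stop("rotation augmentation requires square patches")
  out <- vector("list", 4L)
  for (i in 0L:3L) {
    p <- patch  # keep any extra annotations (e.g. source volume index)
    p$pixels <- px
    p$rotation <- i * 90L
    out[[i + 1L]] <- p
    px <- rotate90(px)
  }
  out
}
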