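#' Specification for a synthetic DBT-like phantom volume
#'
#' The phantom emulates the statistical structure the segmentation method
#' assumes: a smooth tissue-texture background, low-contrast bright masses
#' with diffuse (raised-cosine) margins, and Poisson photon noise. It makes no
#' attempt at anatomical realism.
#'
#' Defaults describe a desk-scale volume: 16 slices of 128 x 128 pixels at
#' 0.1 mm/pixel and 1 mm slice spacing (12.8 mm in-plane field of view), with
#' mass diameters of 2-5 mm, a 35% fractional intensity elevation over the
#' local background, and an expected 5000 photons at unit intensity.
#'
#' @param shape integer vector `(slices, rows, cols)`.
#' @param n_lesions number of masses to place (>= 0).
#' @param diameter_range_mm min/max lesion diameter in mm; must fit inside the
#'   volume extent.
#' @param contrast fractional intensity elevation of a lesion core over its
#'   local background (> 0).
#' @param texture_sigma_px Gaussian blur sigma (pixels) of the background
#'   texture field.
#' @param texture_range intensity band `(lo, hi)` the background texture is
#'   scaled into before lesions and noise are added, emulating the limited
#'   mid-gray dynamic range of soft tissue; the final noisy volume is
#'   rescaled to `[0, 1]`.
#' @param photon_count expected photon count at unit intensity for the Poisson
#'   noise stage (> 0).
#' @param pixel_spacing_mm,slice_spacing_mm spatial calibration.
#' @param edge_softness fraction of the lesion radius over which the
#'   raised-cosine edge decays (0 = hard edge).
#' @param seed integer seed; identical seeds give bit-identical phantoms.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 128L, 128L),
                         n_lesions = 2L,
                         diameter_range_mm = c(2, 5),
                         contrast = 0.35,
                         texture_sigma_px = 6,
                         texture_range = c(0.25, 0.65),
                         photon_count = 5000,
                         pixel_spacing_mm = 0.1,
                         slice_spacing_mm = 1.0,
                         edge_softness = 0.25,
                         seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_lesions >= 0,
            length(diameter_range_mm) == 2L,
            diameter_range_mm[1L] > 0,
            diameter_range_mm[1L] <= diameter_range_mm[2L],
            contrast > 0, photon_count > 0, texture_sigma_px > 0,
            length(texture_range) == 2L, texture_range[1L] >= 0,
            texture_range[1L] < texture_range[2L], texture_range[2L] <= 1,
            pixel_spacing_mm > 0, slice_spacing_mm > 0,
            edge_softness >= 0)
  extent_mm <- c(shape[1L] * slice_spacing_mm,
                 shape[2L] * pixel_spacing_mm,
                 shape[3L] * pixel_spacing_mm)
  if (diameter_range_mm[2L] >= min(extent_mm)) {
    stop(sprintf("max lesion diameter %.3g mm does not fit the minimum volume extent %.3g mm",
                 diameter_range_mm[2L], min(extent_mm)))
  }
  structure(list(shape = shape, n_lesions = as.integer(n_lesions),
                 diameter_range_mm = as.numeric(diameter_range_mm),
                 contrast = contrast, texture_sigma_px = texture_sigma_px,
                 texture_range = as.numeric(texture_range),
                 photon_count = photon_count,
                 pixel_spacing_mm = pixel_spacing_mm,
                 slice_spacing_mm = slice_spacing_mm,
                 edge_softness = edge_softness, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth background texture: white noise blurred in-plane, lightly coupled
# across slices, rescaled to [0, 1] per volume
phantom_background <- function(shape, sigma_px) {
  noise <- array(rnorm(prod(shape)), dim = shape)
  for (s in seq_len(shape[1L])) {
    noise[s, , ] <- EBImage::gblur(noise[s, , ], sigma = sigma_px)
  }
  if (shape[1L] > 2L) {
    sm <- noise
    for (s in 2L:(shape[1L] - 1L)) {
      sm[s, , ] <- 0.25 * noise[s - 1L, , ] + 0.5 * noise[s, , ] + 0.25 * noise[s + 1L, , ]
    }
    noise <- sm
  }
  rng <- range(noise)
  (noise - rng[1L]) / (rng[2L] - rng[1L])
}

# raised-cosine radial profile on normalized radius rho: 1 in the core,
# cosine taper through rho = 1 (where it passes 0.5), 0 beyond
lesion_profile <- function(rho, softness) {
  if (softness <= 0) return((rho <= 1) * 1.0)
  lo <- 1 - softness
  hi <- 1 + softness
  out <- numeric(length(rho))
  out[rho <= lo] <- 1
  mid <- rho > lo & rho < hi
  out[mid] <- 0.5 * (1 + cos(pi * (rho[mid] - lo) / (hi - lo)))
  out
}

#' Generate one synthetic phantom volume with ground truth
#'
#' Builds the blurred-noise background, places non-overlapping soft-edged
#' ellipsoidal lesions of the configured contrast, applies voxelwise Poisson
#' noise at the configured photon scale, and rescales to `[0, 1]`. The mask
#' marks voxels with normalized lesion radius <= 1 (the half-maximum surface
#' of the raised-cosine profile); `lesion_ids` carries one positive integer
#' per lesion.
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = image_volume, mask = mask_volume, lesions = data.frame)`
#'   where `lesions` records centre coordinates and diameters.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shape <- spec$shape
  bg <- phantom_background(shape, spec$texture_sigma_px)
  bg <- spec$texture_range[1L] + diff(spec$texture_range) * bg

  mask <- array(0L, dim = shape)
  ids <- array(0L, dim = shape)
  img <- bg
  lesions <- data.frame(id = integer(), slice = numeric(), row = numeric(),
                        col = numeric(), diameter_mm = numeric())

  if (spec$n_lesions > 0L) {
    placed <- list()
    max_tries <- 200L
    for (k in seq_len(spec$n_lesions)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        dia <- runif(1, spec$diameter_range_mm[1L], spec$diameter_range_mm[2L])
        r_sl <- dia / 2 / spec$slice_spacing_mm   # semi-axis in slices
        r_px <- dia / 2 / spec$pixel_spacing_mm   # in-plane semi-axis in px
        pad <- 1 + spec$edge_softness
        if (2 * r_sl * pad + 2 > shape[1L] || 2 * r_px * pad + 2 > min(shape[2L:3L])) next
        ctr <- c(runif(1, 1 + r_sl * pad, shape[1L] - r_sl * pad),
                 runif(1, 1 + r_px * pad, shape[2L] - r_px * pad),
                 runif(1, 1 + r_px * pad, shape[3L] - r_px * pad))
        clash <- FALSE
        for (p in placed) {
          # normalized centre distance: require the soft shells not to touch
          dvec <- c((ctr[1L] - p$ctr[1L]) / (r_sl + p$r_sl),
                    (ctr[2L] - p$ctr[2L]) / (r_px + p$r_px),
                    (ctr[3L] - p$ctr[3L]) / (r_px + p$r_px))
          if (sqrt(sum(dvec^2)) < pad) { clash <- TRUE; break }
        }
        if (clash) next
        placed[[k]] <- list(ctr = ctr, r_sl = r_sl, r_px = r_px, dia = dia)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(sprintf("could not place lesion %d of %d after %d tries (volume too small)",
                     k, spec$n_lesions, max_tries))
      }
    }
    for (k in seq_along(placed)) {
      p <- placed[[k]]
      s_rng <- max(1L, floor(p$ctr[1L] - p$r_sl * (1 + spec$edge_softness))):
               min(shape[1L], ceiling(p$ctr[1L] + p$r_sl * (1 + spec$edge_softness)))
      r_rng <- max(1L, floor(p$ctr[2L] - p$r_px * (1 + spec$edge_softness))):
               min(shape[2L], ceiling(p$ctr[2L] + p$r_px * (1 + spec$edge_softness)))
      c_rng <- max(1L, floor(p$ctr[3L] - p$r_px * (1 + spec$edge_softness))):
               min(shape[3L], ceiling(p$ctr[3L] + p$r_px * (1 + spec$edge_softness)))
      rho <- sqrt(outer(outer(((s_rng - p$ctr[1L]) / p$r_sl)^2,
                              ((r_rng - p$ctr[2L]) / p$r_px)^2, `+`),
                        ((c_rng - p$ctr[3L]) / p$r_px)^2, `+`))
      prof <- array(lesion_profile(as.vector(rho), spec$edge_softness), dim = dim(rho))
      img[s_rng, r_rng, c_rng] <- img[s_rng, r_rng, c_rng] +
        spec$contrast * mean(bg) * prof
      inside <- rho <= 1
      mask[s_rng, r_rng, c_rng][inside] <- 1L
      ids[s_rng, r_rng, c_rng][inside] <- k
      lesions <- rbind(lesions, data.frame(id = k, slice = p$ctr[1L],
                                           row = p$ctr[2L], col = p$ctr[3L],
                                           diameter_mm = p$dia))
    }
  }

  counts <- array(rpois(length(img), lambda = pmax(img, 0) * spec$photon_count),
                  dim = dim(img))
  noisy <- counts / spec$photon_count
  if (max(noisy) > 0) noisy <- noisy / max(noisy)

  list(image = image_volume(noisy, spec$pixel_spacing_mm, spec$slice_spacing_mm),
       mask = mask_volume(mask, ids),
       lesions = lesions)
}

#' Generate a dataset of phantom volumes
#'
#' Per-volume seeds are derived deterministically from the master seed, and
#' the lesion count of each volume is sampled uniformly from
#' `n_lesions_range`.
#'
#' @param n_volumes number of volumes (>= 1).
#' @param spec_template a [phantom_spec()] supplying everything except the
#'   seed and lesion count.
#' @param seed master seed.
#' @param n_lesions_range inclusive integer range for per-volume lesion count.
#' @return List of `n_volumes` results of [generate_phantom()].
#' @export
generate_dataset <- function(n_volumes, spec_template = phantom_spec(),
                             seed = 1L, n_lesions_range = c(1L, 3L)) {
  stopifnot(n_volumes >= 1, length(n_lesions_range) == 2L,
            n_lesions_range[1L] <= n_lesions_range[2L])
  set.seed(seed)
  vol_seeds <- sample.int(.Machine$integer.max - 1L, n_volumes)
  n_les <- sample(seq.int(n_lesions_range[1L], n_lesions_range[2L]),
                  n_volumes, replace = TRUE)
  out <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    spec_i <- spec_template
    spec_i$seed <- vol_seeds[i]
    spec_i$n_lesions <- as.integer(n_les[i])
    out[[i]] <- tryCatch(generate_phantom(spec_i), error = function(e) {
      stop(sprintf("volume %d: %s", i, conditionMessage(e)))
    })
  }
  out
}
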