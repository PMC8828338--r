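test_that("sliding-window origin enumeration matches the exhaustive oracle", {
  # single placement: patch as large as the slice
  o1 <- enumerate_origins(256L, 256L, 256L, 28L)
  expect_identical(nrow(o1), 1L)
  expect_identical(o1[1L, ], c(row = 1L, col = 1L))

  # full-scale slice geometry
  o2 <- enumerate_origins(1200L, 901L, 256L, 28L)
  expect_identical(nrow(o2), 816L)
  expect_identical(nrow(o2), nrow(oracle_origins(1200L, 901L, 256L, 28L)))

  o3 <- enumerate_origins(300L, 300L, 256L, 28L)
  expect_identical(nrow(o3), 4L)

  # randomized property: equality with the brute-force placement set
  set.seed(100)
  for (i in 1:100) {
    H <- sample(10:200, 1)
    W <- sample(10:200, 1)
    P <- sample(seq_len(min(H, W)), 1)
    s <- sample(1:P, 1)
    got <- enumerate_origins(H, W, P, s)
    want <- oracle_origins(H, W, P, s)
    expect_identical(unname(got), unname(want))
    expect_identical(nrow(got),
                     as.integer((((H - P) %/% s) + 1) * (((W - P) %/% s) + 1)))
  }

  expect_error(enumerate_origins(100L, 100L, 128L, 16L), "exceeds")
})

test_that("patches are labelled by the mask value at their central pixel", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 12L))
  vol <- ph$image

  zero_mask <- mask_volume(array(0L, dim = dim(vol$voxels)))
  pz <- extract_patches(vol, zero_mask, 16L, 8L)
  expect_true(all(vapply(pz, `[[`, integer(1), "label") == 0L))

  ones_mask <- mask_volume(array(1L, dim = dim(vol$voxels)))
  po <- extract_patches(vol, ones_mask, 16L, 8L)
  expect_true(all(vapply(po, `[[`, integer(1), "label") == 1L))

  # positive count equals the number of enumerated centres inside the mask
  pp <- extract_patches(vol, ph$mask, 16L, 8L)
  origins <- enumerate_origins(64L, 64L, 16L, 8L)
  expected_pos <- 0L
  for (s in 1:8) {
    for (i in seq_len(nrow(origins))) {
      ctr <- origins[i, ] + 8L  # floor(16 / 2)
      expected_pos <- expected_pos + ph$mask$labels[s, ctr[1L], ctr[2L]]
    }
  }
  expect_identical(sum(vapply(pp, `[[`, integer(1), "label")), expected_pos)

  # patch pixels are the stated window of the source slice
  p1 <- pp[[37]]
  expect_identical(p1$pixels,
                   vol$voxels[p1$slice,
                              p1$origin[1]:(p1$origin[1] + 15L),
                              p1$origin[2]:(p1$origin[2] + 15L)])

  expect_error(extract_patches(vol, mask_volume(array(0L, c(2L, 4L, 4L)))),
               "differ")
})

test_that("balanced epoch sampling equalizes classes and is seeded", {
  mk <- function(label, n) {
    lapply(seq_len(n), function(i) {
      structure(list(pixels = matrix(i, 4, 4), slice = 1L, origin = c(1L, 1L),
                     label = label, rotation = 0L), class = "dbt_patch")
    })
  }
  patches <- c(mk(1L, 10), mk(0L, 1000))

  s <- balanced_epoch_sample(patches, 50L, seed = 3L)
  labs <- vapply(s, `[[`, integer(1), "label")
  expect_identical(sum(labs == 1L), 50L)
  expect_identical(sum(labs == 0L), 50L)

  s2 <- balanced_epoch_sample(patches, 50L, seed = 3L)
  expect_identical(s, s2)
  s3 <- balanced_epoch_sample(patches, 50L, seed = 4L)
  expect_false(identical(s, s3))

  expect_error(balanced_epoch_sample(mk(0L, 5), 3L), "positive")
})

test_that("right-angle rotation augmentation preserves labels and composes to identity", {
  set.seed(5)
  px <- matrix(runif(16), 4L, 4L)
  patch <- structure(list(pixels = px, slice = 1L, origin = c(1L, 1L),
                          label = 1L, rotation = 0L, volume = 2L),
                     class = "dbt_patch")
  aug <- augment_rotations(patch)
  expect_length(aug, 4L)
  expect_identical(vapply(aug, `[[`, integer(1), "rotation"),
                   c(0L, 90L, 180L, 270L))
  expect_true(all(vapply(aug, `[[`, integer(1), "label") == 1L))
  expect_true(all(vapply(aug, `[[`, integer(1), "volume") == 2L))

  # 90-degree oracle: out[r, c] = in[c, P + 1 - r]
  r90 <- aug[[2]]$pixels
  for (r in 1:4) for (c_ in 1:4) expect_identical(r90[r, c_], px[c_, 5L - r])

  # rotating four times composes to the identity
  p4 <- augment_rotations(structure(list(pixels = aug[[4]]$pixels, slice = 1L,
                                         origin = c(1L, 1L), label = 1L,
                                         rotation = 0L), class = "dbt_patch"))
  expect_identical(p4[[2]]$pixels, px)

  # constant patches differ only in the rotation tag
  cp <- structure(list(pixels = matrix(1, 4, 4), slice = 1L, origin = c(1L, 1L),
                       label = 0L, rotation = 0L), class = "dbt_patch")
  expect_true(all(vapply(augment_rotations(cp),
                         function(p) all(p$pixels == 1), logical(1))))

  bad <- structure(list(pixels = matrix(0, 3, 4)), class = "dbt_patch")
  expect_error(augment_rotations(bad), "square")
})
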