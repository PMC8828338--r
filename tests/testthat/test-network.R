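test_that("dilated convolution reproduces hand-computable cases", {
  set.seed(3)
  f <- matrix(rnorm(256), 16L, 16L)

  # delta kernel is the identity for every dilation
  delta <- matrix(0, 3L, 3L)
  delta[2L, 2L] <- 1
  for (d in c(1L, 3L, 7L)) {
    expect_equal(dilated_conv2d(f, delta, d), f, tolerance = 1e-12)
  }

  # 3x3 averaging kernel, d = 2, on a centred impulse: nine outputs of 1/9
  # on the {-2, 0, 2}^2 lattice around the impulse
  imp <- matrix(0, 15L, 15L)
  imp[8L, 8L] <- 1
  avg <- matrix(1 / 9, 3L, 3L)
  out <- dilated_conv2d(imp, avg, 2L)
  nz <- which(out != 0, arr.ind = TRUE)
  expect_identical(nrow(nz), 9L)
  expect_true(all(abs(out[nz] - 1 / 9) < 1e-12))
  expect_setequal(unique(nz[, 1L]), c(6L, 8L, 10L))
  expect_setequal(unique(nz[, 2L]), c(6L, 8L, 10L))

  expect_error(dilated_conv2d(f, matrix(0, 2L, 2L), 1L), "odd")
  expect_error(dilated_conv2d(f, delta, 0L), ">= 1")
})

test_that("the network preserves spatial resolution and initializes deterministically", {
  m <- build_network(seed = 1L)
  x <- array(rnorm(64 * 64), c(64L, 64L, 1L, 1L))
  expect_identical(dim(net_forward(m, x)$logits), c(64L, 64L, 1L, 2L))

  m2 <- build_network(seed = 1L)
  expect_identical(lapply(m$layers, `[[`, "W"), lapply(m2$layers, `[[`, "W"))
  m3 <- build_network(seed = 2L)
  expect_false(identical(m$layers[[1L]]$W, m3$layers[[1L]]$W))

  expect_error(architecture_spec(list(layer_spec(3L, 1L, 8L),
                                      layer_spec(3L, 16L, 2L))),
               "channel mismatch")
  expect_error(architecture_spec(list(layer_spec(1L, 1L, 3L,
                                                 batchnorm = FALSE))),
               "2 channels")
})

test_that("analytic receptive field matches layer arithmetic and the empirical footprint", {
  one <- architecture_spec(list(layer_spec(3L, 1L, 4L),
                                layer_spec(1L, 4L, 2L, batchnorm = FALSE,
                                           activation = "none")))
  expect_identical(unname(receptive_field(one)), c(3L, 3L))

  two <- architecture_spec(list(layer_spec(3L, 1L, 4L, dilation = 1L),
                                layer_spec(3L, 4L, 4L, dilation = 2L),
                                layer_spec(1L, 4L, 2L, batchnorm = FALSE,
                                           activation = "none")))
  expect_identical(unname(receptive_field(two)), c(7L, 7L))

  expect_identical(unname(receptive_field(architecture_spec())), c(67L, 67L))

  # empirical footprint: with positive weights, zero biases and identity-like
  # evaluation batch norm, perturbing one input pixel changes exactly the
  # receptive-field window of the output map
  footprint <- function(spec) {
    m <- build_network(spec, seed = 1L)
    for (i in seq_along(m$layers)) m$layers[[i]]$W <- abs(m$layers[[i]]$W) + 0.01
    n <- 33L
    base <- array(1, c(n, n, 1L, 1L))
    pert <- base
    ctr <- (n + 1L) %/% 2L
    pert[ctr, ctr, 1L, 1L] <- 2
    d <- abs(net_forward(m, pert)$logits[, , 1L, 2L] -
             net_forward(m, base)$logits[, , 1L, 2L])
    rows <- range(which(apply(d > 1e-12, 1L, any)))
    diff(rows) + 1L
  }
  expect_identical(footprint(two), 7L)
})

test_that("dense prediction yields calibrated two-class probabilities", {
  m <- build_network(seed = 3L)
  vol <- image_volume(array(runif(3 * 100 * 90), c(3L, 100L, 90L)))
  hm <- predict_heatmap(m, vol)
  expect_identical(dim(hm$probabilities), c(3L, 100L, 90L))
  expect_gte(min(hm$probabilities), 0)
  expect_lte(max(hm$probabilities), 1)

  # zeroing the final layer gives equal logits, hence probability 1/2
  m0 <- m
  last <- length(m0$layers)
  m0$layers[[last]]$W[] <- 0
  m0$layers[[last]]$b[] <- 0
  hm0 <- predict_heatmap(m0, vol)
  expect_true(all(abs(hm0$probabilities - 0.5) < 1e-12))
})

test_that("the network is translation-equivariant away from borders", {
  m <- build_network(seed = 6L)
  n <- 128L
  mk <- function(r, c_) {
    x <- array(0, c(n, n, 1L, 1L))
    x[r, c_, 1L, 1L] <- 1
    net_forward(m, x)$logits[, , 1L, 2L]
  }
  a <- mk(60L, 60L)
  b <- mk(68L, 64L)
  # compare the centred windows around each impulse (RF 67 stays inside)
  expect_equal(a[(60 - 33):(60 + 33), (60 - 33):(60 + 33)],
               b[(68 - 33):(68 + 33), (64 - 33):(64 + 33)],
               tolerance = 1e-9)
})

test_that("batched layer convolution agrees with the literal dilated convolution", {
  # the network's cross-correlation layer equals true convolution of the
  # flipped kernel, checked against the literal operator
  set.seed(17)
  f <- matrix(rnorm(24 * 24), 24L, 24L)
  r <- matrix(rnorm(9), 3L, 3L)
  for (d in c(1L, 2L, 4L)) {
    x <- array(f, c(24L, 24L, 1L, 1L))
    w <- array(r[3:1, 3:1], c(3L, 3L, 1L, 1L))
    got <- dbtseg:::conv_fwd_cpp(x, w, 0, d)[, , 1L, 1L]
    expect_equal(got, dilated_conv2d(f, r, d), tolerance = 1e-12)
  }
})
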