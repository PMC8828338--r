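test_that("the f_alpha measure reproduces closed-form overlap cases", {
  t_ <- c(1, 1, 0, 0, 1, 0)
  expect_identical(f_alpha_measure(t_, t_, alpha = 1), 1)
  expect_identical(f_alpha_measure(c(0, 0, 1, 1, 0, 0), t_, alpha = 1), 0)
  expect_identical(f_alpha_measure(c(1, 1, 0, 0), c(1, 0, 1, 0), alpha = 1), 0.5)

  expect_identical(dice_loss(t_, t_), 0)
  expect_identical(dice_loss(c(0, 0, 1, 1, 0, 0), t_), 1)
  expect_identical(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)

  # undefined 0/0 errors unless smoothed
  expect_error(f_alpha_measure(c(0, 0), c(0, 0)), "0/0")
  expect_identical(f_alpha_measure(c(0, 0), c(0, 0), smooth = 1e-6), 1)
  expect_error(f_alpha_measure(numeric(0), numeric(0)), "empty")
  expect_error(f_alpha_measure(c(1, 0), c(1, 0, 1)), "same number")
})

test_that("f_alpha is symmetric, bounded, and has a correct analytic gradient", {
  set.seed(19)
  for (i in 1:20) {
    S <- runif(40)
    T_ <- rbinom(40, 1, 0.3)
    if (sum(T_) == 0) T_[1] <- 1
    # bounded in [0, 1] for alpha = 1
    v <- f_alpha_measure(S, T_, alpha = 1)
    expect_gte(v, 0)
    expect_lte(v, 1)
    # symmetric for binary arguments
    Sb <- rbinom(40, 1, 0.5)
    if (sum(Sb) + sum(T_) > 0) {
      expect_equal(f_alpha_measure(Sb, T_), f_alpha_measure(T_, Sb))
    }
    # gradient vs central finite differences
    g <- f_alpha_grad(S, T_, alpha = 1)
    idx <- sample(40, 5)
    eps <- 1e-6
    for (j in idx) {
      Sp <- S; Sp[j] <- Sp[j] + eps
      Sm <- S; Sm[j] <- Sm[j] - eps
      num <- (f_alpha_measure(Sp, T_) - f_alpha_measure(Sm, T_)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-4)
    }
  }
})

test_that("volume-level folds partition the data into near-equal parts", {
  f10 <- make_folds(1:20, k = 10L, seed = 1L)
  expect_length(f10, 10L)
  expect_true(all(lengths(f10) == 2L))
  expect_setequal(unlist(f10), 1:20)

  f23 <- make_folds(1:23, k = 10L, seed = 2L)
  expect_true(all(lengths(f23) %in% c(2L, 3L)))
  expect_identical(sum(lengths(f23)), 23L)
  expect_setequal(unlist(f23), 1:23)  # disjoint union = all volumes

  expect_identical(make_folds(1:23, 10L, seed = 2L), f23)
  expect_error(make_folds(1:5, k = 10L), "at least")
})

small_arch <- function() {
  architecture_spec(list(
    layer_spec(3L, 1L, 6L, dilation = 1L),
    layer_spec(3L, 6L, 6L, dilation = 2L),
    layer_spec(1L, 6L, 2L, batchnorm = FALSE, activation = "none")))
}

toy_training_setup <- function(seed = 7L) {
  ph <- generate_phantom(phantom_spec(shape = c(8L, 64L, 64L), n_lesions = 2L,
                                      diameter_range_mm = c(1.2, 2),
                                      seed = seed))
  cfg <- default_config("desk")
  cfg$patch_size <- 16L
  cfg$stride <- 8L
  cfg$per_class_n <- 4L
  cfg$batch_size <- 8L
  cfg$epochs <- 4L
  cfg$seed <- seed
  patches <- extract_patches(ph$image, ph$mask, cfg$patch_size, cfg$stride)
  for (i in seq_along(patches)) patches[[i]]$volume <- 1L
  list(cfg = cfg, patches = patches, masks = list(ph$mask))
}

test_that("training improves the loss on a separable toy problem, deterministically", {
  setup <- toy_training_setup()
  m0 <- build_network(small_arch(), seed = 7L)

  fit1 <- train(m0, setup$patches, setup$masks, setup$cfg)
  expect_lt(fit1$trace[length(fit1$trace)], fit1$trace[1L])

  fit2 <- train(m0, setup$patches, setup$masks, setup$cfg)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$model$layers[[1L]]$W, fit2$model$layers[[1L]]$W)
})

test_that("a zero learning rate leaves the weights untouched", {
  setup <- toy_training_setup()
  setup$cfg$learning_rate <- 0
  setup$cfg$epochs <- 2L
  m0 <- build_network(small_arch(), seed = 8L)
  fit <- train(m0, setup$patches, setup$masks, setup$cfg)
  for (i in seq_along(m0$layers)) {
    expect_identical(fit$model$layers[[i]]$W, m0$layers[[i]]$W)
    expect_identical(fit$model$layers[[i]]$b, m0$layers[[i]]$b)
  }
})

test_that("the loss gradient backpropagated to the input matches finite differences", {
  # end-to-end check through softmax, batch norm and dilated convolutions
  m <- build_network(small_arch(), seed = 11L)
  set.seed(11)
  x <- array(runif(12 * 12 * 2), c(12L, 12L, 2L, 1L))
  t_ <- array(rbinom(12 * 12 * 2, 1, 0.2), c(12L, 12L, 2L))

  loss_of <- function(xx) {
    fw <- net_forward(m, xx, train = TRUE)
    s <- plogis(fw$logits[, , , 2L] - fw$logits[, , , 1L])
    dice_loss(s, t_, smooth = 1e-6)
  }
  fw <- net_forward(m, x, train = TRUE)
  s <- plogis(fw$logits[, , , 2L] - fw$logits[, , , 1L])
  gs <- -f_alpha_grad(s, t_, smooth = 1e-6)
  dmass <- gs * s * (1 - s)
  dlogits <- array(0, dim = dim(fw$logits))
  dlogits[, , , 2L] <- dmass
  dlogits[, , , 1L] <- -dmass
  dx <- net_backward(m, fw$cache, dlogits)$dx

  eps <- 1e-5
  set.seed(12)
  for (j in sample(length(x), 8)) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    num <- (loss_of(xp) - loss_of(xm)) / (2 * eps)
    expect_equal(dx[j], num, tolerance = 1e-4)
  }
})
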