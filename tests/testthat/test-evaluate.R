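mk_mask <- function(arr) mask_volume(arr)

test_that("confusion counts and pixel metrics follow their definitions", {
  truth <- array(0L, c(1L, 4L, 4L))
  truth[1L, 1L, 1:3] <- 1L                # 3 true voxels
  pred <- array(0L, c(1L, 4L, 4L))
  pred[1L, 1L, 1:2] <- 1L                 # hits 2 of them
  pred[1L, 2L, 1L] <- 1L                  # 1 spurious voxel
  cts <- confusion(mk_mask(pred), mk_mask(truth))
  expect_identical(cts, list(TP = 2L, FP = 1L, TN = 12L, FN = 1L))

  # perfect and inverted predictions
  p_eq <- confusion(mk_mask(truth), mk_mask(truth))
  expect_identical(p_eq$FP + p_eq$FN, 0L)
  p_inv <- confusion(mk_mask(1L - truth), mk_mask(truth))
  expect_identical(p_inv$TP + p_inv$TN, 0L)

  # worked confusion example
  m <- acc_sen_spe(list(TP = 8L, FN = 2L, FP = 5L, TN = 85L))
  expect_equal(unname(m["ACC"]), 0.93)
  expect_equal(unname(m["SEN"]), 0.80)
  expect_equal(unname(m["SPE"]), 85 / 90)

  expect_equal(unname(acc_sen_spe(list(TP = 5L, FN = 0L, FP = 0L, TN = 7L))),
               c(1, 1, 1))
  expect_error(acc_sen_spe(list(TP = 0L, FN = 0L, FP = 2L, TN = 5L)), "SEN")
  expect_error(confusion(mk_mask(pred), mk_mask(array(0L, c(1L, 2L, 2L)))),
               "differ")
})

test_that("trapezoidal ROC AUC equals the rank statistic", {
  truth <- array(0L, c(1L, 4L, 4L))
  truth[1L, 1:2, 1:2] <- 1L

  # scores identical to truth -> perfect separation
  expect_identical(roc_auc(array(as.numeric(truth), dim = dim(truth)),
                           mk_mask(truth)), 1)

  # reversing the scores complements the AUC
  set.seed(41)
  s <- array(runif(16), dim = dim(truth))
  a <- roc_auc(s, mk_mask(truth))
  expect_equal(roc_auc(1 - s, mk_mask(truth)), 1 - a, tolerance = 1e-12)

  # rank-statistic oracle on randomized inputs, with and without ties
  for (i in 1:20) {
    n <- sample(20:60, 1)
    sc <- if (i %% 2 == 0) round(runif(n), 1) else runif(n)
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0) lb[1] <- 1L
    if (sum(lb) == n) lb[1] <- 0L
    got <- roc_auc(array(sc, c(n, 1L, 1L)), array(as.integer(lb), c(n, 1L, 1L)))
    expect_equal(got, oracle_rank_auc(sc, lb), tolerance = 1e-9)
  }

  # independent noise scores hover near 1/2
  set.seed(42)
  big_t <- array(rbinom(20000, 1, 0.3), c(20L, 100L, 10L))
  big_s <- array(runif(20000), c(20L, 100L, 10L))
  expect_lt(abs(roc_auc(big_s, big_t) - 0.5), 0.02)

  expect_error(roc_auc(s, mk_mask(array(0L, dim = dim(truth)))), "single class")
})

# build a heatmap volume with rectangular blobs of given probability
blob_heatmap <- function(dims, blobs) {
  p <- array(0, dim = dims)
  for (b in blobs) p[b$s, b$r, b$c] <- b$prob
  heatmap_volume(p)
}

test_that("FROC counts identified lesions and false-positive components", {
  cfg <- default_config("desk")
  dims <- c(8L, 64L, 64L)

  # two volumes, three lesions; predictions hit two lesions and add four
  # spurious components -> TPR = 2/3, FPV = 4/2 = 2
  ids1 <- array(0L, dims)
  ids1[2:4, 5:14, 5:14] <- 1L
  ids1[2:4, 40:49, 40:49] <- 2L
  truth1 <- mask_volume((ids1 > 0L) * 1L, ids1)
  ids2 <- array(0L, dims)
  ids2[5:7, 20:29, 20:29] <- 3L
  truth2 <- mask_volume((ids2 > 0L) * 1L, ids2)

  blob <- function(s, r, c_) list(s = s, r = r, c = c_, prob = 0.9)
  hm1 <- blob_heatmap(dims, list(blob(2:4, 6:13, 6:13),      # hits lesion 1
                                 blob(2:3, 52:58, 52:58)))   # spurious (98 vox)
  hm2 <- blob_heatmap(dims, list(blob(5:7, 21:28, 21:28),    # hits lesion 3
                                 blob(1:2, 1:7, 1:7),        # spurious
                                 blob(1:2, 50:56, 50:56),    # spurious
                                 blob(6:7, 1:7, 40:46)))     # spurious
  curve <- froc(list(hm1, hm2), list(truth1, truth2),
                thresholds = c(0.8, 0.5), cfg = cfg)
  expect_equal(curve$tpr, c(2 / 3, 2 / 3))
  expect_equal(curve$fpv, c(2, 2))

  # perfect predictions: TPR 1 at 0 FPV; empty predictions: all zero
  hp <- list(heatmap_volume(array(as.numeric(ids1 > 0L), dims)),
             heatmap_volume(array(as.numeric(ids2 > 0L), dims)))
  cp <- froc(hp, list(truth1, truth2), thresholds = c(0.9, 0.5), cfg = cfg)
  expect_true(all(cp$tpr == 1))
  expect_true(all(cp$fpv == 0))

  ce <- froc(list(heatmap_volume(array(0, dims)), heatmap_volume(array(0, dims))),
             list(truth1, truth2), thresholds = c(0.9, 0.5), cfg = cfg)
  expect_true(all(ce$tpr == 0))
  expect_true(all(ce$fpv == 0))

  # TPR is non-decreasing as the threshold falls (graded heatmap)
  grad <- blob_heatmap(dims, list(list(s = 2:4, r = 5:14, c = 5:14, prob = 0.9),
                                  list(s = 2:4, r = 40:49, c = 40:49, prob = 0.4)))
  cg <- froc(list(grad), list(truth1), thresholds = seq(0.95, 0.05, -0.1),
             cfg = cfg)
  expect_true(all(diff(cg$tpr) >= 0))

  expect_error(froc(list(hm1), list(mask_volume((ids1 > 0L) * 1L))),
               "lesion_ids")
  op <- froc_operating_point(cg, max_fpv = 4)
  expect_equal(op$tpr, 1)
})

test_that("cross-validation summaries aggregate fold metrics", {
  r1 <- c(ACC = 0.8, SEN = 0.7)
  r2 <- c(ACC = 0.9, SEN = 0.8)
  rep2 <- crossval_report(list(r1, r2))
  expect_equal(unname(rep2$mean["ACC"]), 0.85)
  expect_equal(unname(rep2$sd["ACC"]), sd(c(0.8, 0.9)))

  rep_same <- crossval_report(list(r1, r1, r1))
  expect_true(all(rep_same$sd == 0))

  rep_one <- crossval_report(list(r1))
  expect_equal(unname(rep_one$mean), unname(r1))
})
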