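#' End-to-end synthetic segmentation experiment
#'
#' Generates a seeded dataset of phantom volumes, preprocesses every volume,
#' extracts labelled patches from the training volumes, trains the dilated
#' fully convolutional network under the Dice (`f_alpha`) loss, predicts
#' dense mass-probability heatmaps for the held-out volumes, postprocesses
#' them into final masks, and scores the result at pixel level (Dice, ACC /
#' SEN / SPE, ROC AUC) and lesion level (FROC). An untrained copy of the
#' network is scored the same way as a floor reference.
#'
#' Everything is deterministic under `seed`: the phantom data, the weight
#' initialization, the per-epoch patch sampling, and hence the final masks.
#'
#' @param seed master seed for data generation and training.
#' @param n_volumes total phantom volumes to generate.
#' @param n_test number of volumes held out for evaluation (the last
#'   `n_test` of the generated list).
#' @param cfg a `run_config`; desk profile by default.
#' @param spec_template [phantom_spec()] describing the phantom population.
#' @param n_lesions_range per-volume lesion count range.
#' @param epochs optional override of `cfg$epochs`.
#' @return List with elements `model`, `trace` (per-epoch loss),
#'   `heatmaps`, `masks` (final predicted masks), `truths`, `metrics`
#'   (named vector: mean Dice, ACC, SEN, SPE, pooled AUC, lesion TPR and FPV
#'   at a 4-FPV budget), `untrained_metrics`, and `froc` (the full curve).
#' @export
run_phantom_experiment <- function(seed = 1L,
                                   n_volumes = 12L,
                                   n_test = 3L,
                                   cfg = default_config("desk"),
                                   spec_template = phantom_spec(),
                                   n_lesions_range = c(1L, 3L),
                                   epochs = NULL) {
  stopifnot(n_test >= 1L, n_volumes > n_test)
  cfg$seed <- as.integer(seed)
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)

  dataset <- generate_dataset(n_volumes, spec_template, seed = seed,
                              n_lesions_range = n_lesions_range)
  train_idx <- seq_len(n_volumes - n_test)
  test_idx <- setdiff(seq_len(n_volumes), train_idx)

  pre <- lapply(dataset, function(d) preprocess_volume(d$image, cfg))

  patches <- list()
  masks <- lapply(dataset, `[[`, "mask")
  for (v in train_idx) {
    pv <- extract_patches(pre[[v]], dataset[[v]]$mask, cfg$patch_size, cfg$stride)
    for (i in seq_along(pv)) pv[[i]]$volume <- v
    patches <- c(patches, pv)
  }

  model0 <- build_network(architecture_spec(channels = cfg$channels), seed = seed)
  fit <- train(model0, patches, masks, cfg)
  gc(FALSE)

  score_model <- function(model, with_froc = TRUE) {
    hms <- lapply(test_idx, function(v) {
      hm <- predict_heatmap(model, pre[[v]])
      gc(FALSE)
      hm
    })
    preds <- lapply(hms, postprocess_heatmap, cfg = cfg)
    truths <- lapply(test_idx, function(v) dataset[[v]]$mask)
    dice <- mapply(function(p, t_) {
      f_alpha_measure(p$labels, t_$labels, alpha = 1, smooth = 1e-9)
    }, preds, truths)
    pooled_scores <- array(unlist(lapply(hms, `[[`, "probabilities")))
    pooled_truth <- array(unlist(lapply(truths, `[[`, "labels")))
    auc <- roc_auc(array(pooled_scores, dim = c(length(pooled_scores), 1, 1)),
                   array(as.integer(pooled_truth), dim = c(length(pooled_truth), 1, 1)))
    cts <- confusion(
      mask_volume(array(unlist(lapply(preds, `[[`, "labels")),
                        dim = c(length(pooled_truth), 1, 1))),
      mask_volume(array(as.integer(pooled_truth), dim = c(length(pooled_truth), 1, 1))))
    pix <- acc_sen_spe(cts)
    metrics <- c(dice = mean(dice), pix, AUC = auc)
    curve <- NULL
    if (with_froc) {
      curve <- froc(hms, truths, cfg = cfg)
      op <- froc_operating_point(curve, max_fpv = 4)
      metrics <- c(metrics, lesion_tpr = op$tpr,
                   fpv = ifelse(is.na(op$fpv), 0, op$fpv))
    }
    list(heatmaps = hms, masks = preds, truths = truths, froc = curve,
         metrics = metrics)
  }

  trained_scores <- score_model(fit$model)
  untrained_scores <- score_model(model0, with_froc = FALSE)

  list(model = fit$model, trace = fit$trace,
       heatmaps = trained_scores$heatmaps,
       masks = trained_scores$masks,
       truths = trained_scores$truths,
       froc = trained_scores$froc,
       metrics = trained_scores$metrics,
       untrained_metrics = untrained_scores$metrics,
       cfg = cfg, test_idx = test_idx)
}
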