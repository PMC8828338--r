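#' Voxelwise confusion counts between predicted and true masks
#'
#' @param pred,truth aligned binary [mask_volume()]s.
#' @return `list(TP, FP, TN, FN)` of voxel counts.
#' @export
confusion <- function(pred, truth) {
  stopifnot(inherits(pred, "mask_volume"), inherits(truth, "mask_volume"))
  if (!identical(dim(pred$labels), dim(truth$labels))) {
    stop("prediction and truth shapes differ")
  }
  p <- pred$labels == 1L
  t_ <- truth$labels == 1L
  list(TP = sum(p & t_), FP = sum(p & !t_), TN = sum(!p & !t_), FN = sum(!p & t_))
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. A metric whose denominator is zero is undefined
#' and raises an error naming the metric.
#'
#' @param counts `list(TP, FP, TN, FN)` from [confusion()].
#' @return Named numeric vector `c(ACC, SEN, SPE)`.
#' @export
acc_sen_spe <- function(counts) {
  with(counts, {
    total <- TP + TN + FP + FN
    if (total == 0) stop("ACC undefined: no voxels evaluated")
    if (TP + FN == 0) stop("SEN undefined: no positive voxels in truth")
    if (TN + FP == 0) stop("SPE undefined: no negative voxels in truth")
    c(ACC = (TP + TN) / total, SEN = TP / (TP + FN), SPE = TN / (TN + FP))
  })
}

#' Pixel-level ROC AUC of a heatmap against a binary truth
#'
#' Builds the ROC curve over all unique score thresholds and integrates it
#' with the trapezoidal rule; this equals the Mann-Whitney rank statistic
#' (ties handled by the half-step of the trapezoid).
#'
#' @param hm a [heatmap_volume()] (or 3D probability array).
#' @param truth a [mask_volume()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(hm, truth) {
  scores <- if (inherits(hm, "heatmap")) hm$probabilities else hm
  labels <- if (inherits(truth, "mask_volume")) truth$labels else truth
  stopifnot(identical(dim(scores), dim(labels)))
  y <- as.vector(labels) == 1L
  s <- as.vector(scores)
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: truth contains a single class")
  }
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  s <- s[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # collapse tied scores
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

match_components <- function(pred_lab, lesion_ids, rule = "any_overlap",
                             min_fraction = 0.1) {
  n_comp <- max(pred_lab)
  lesion_set <- setdiff(unique(as.vector(lesion_ids)), 0L)
  hit_lesions <- integer(0)
  fp_components <- 0L
  for (cc in seq_len(n_comp)) {
    in_comp <- pred_lab == cc
    overlap <- lesion_ids[in_comp]
    overlap <- overlap[overlap > 0L]
    matched <- switch(rule,
      any_overlap = length(overlap) > 0L,
      fraction = length(overlap) >= min_fraction * sum(in_comp),
      centroid = {
        idx <- which(in_comp, arr.ind = TRUE)
        ctr <- round(colMeans(idx))
        lesion_ids[ctr[1L], ctr[2L], ctr[3L]] > 0L
      })
    if (matched) {
      hit_lesions <- union(hit_lesions, unique(overlap))
    } else {
      fp_components <- fp_components + 1L
    }
  }
  list(n_lesions = length(lesion_set), hit = length(intersect(hit_lesions, lesion_set)),
       fp = fp_components)
}

#' FROC curve: lesion-level TPR vs false positives per volume
#'
#' For each decision threshold (sweeping from high to low), every heatmap is
#' binarized and postprocessed with the deployed pipeline (cluster removal
#' and median smoothing), predicted components are matched against lesion
#' instances, and the pooled lesion true-positive rate and mean
#' false-positive component count per volume are recorded. A lesion counts
#' as identified when at least one predicted-component voxel overlaps it
#' (default rule); alternatives are overlap-fraction and
#' centroid-inside-lesion matching.
#'
#' @param heatmaps list of [heatmap_volume()]s, one per volume.
#' @param truths list of [mask_volume()]s with `lesion_ids` set.
#' @param thresholds strictly decreasing probability thresholds.
#' @param cfg a `run_config` supplying the postprocessing parameters and the
#'   `match_rule`.
#' @return `data.frame(threshold, tpr, fpv)` of class `froc_curve`.
#' @export
froc <- function(heatmaps, truths, thresholds = seq(0.95, 0.05, by = -0.05),
                 cfg = default_config("desk")) {
  stopifnot(length(heatmaps) == length(truths),
            all(diff(thresholds) < 0))
  for (t_ in truths) {
    if (is.null(t_$lesion_ids)) stop("every truth volume must carry lesion_ids")
  }
  n_vol <- length(heatmaps)
  out <- data.frame(threshold = thresholds, tpr = NA_real_, fpv = NA_real_)
  for (i in seq_along(thresholds)) {
    cfg_i <- cfg
    cfg_i$threshold <- thresholds[i]
    tot_lesions <- 0L
    tot_hit <- 0L
    tot_fp <- 0L
    for (v in seq_len(n_vol)) {
      pred <- postprocess_heatmap(heatmaps[[v]], cfg_i)
      lab <- label_components(pred, cfg$connectivity, "3d")
      m <- match_components(lab, truths[[v]]$lesion_ids, cfg$match_rule)
      tot_lesions <- tot_lesions + m$n_lesions
      tot_hit <- tot_hit + m$hit
      tot_fp <- tot_fp + m$fp
    }
    out$tpr[i] <- if (tot_lesions > 0L) tot_hit / tot_lesions else 0
    out$fpv[i] <- tot_fp / n_vol
  }
  class(out) <- c("froc_curve", "data.frame")
  out
}

#' Best lesion TPR on an FROC curve subject to a false-positive budget
#'
#' @param curve a `froc_curve` from [froc()].
#' @param max_fpv largest acceptable false-positive count per volume.
#' @return `list(tpr, fpv, threshold)` of the best admissible point (TPR 0
#'   when no point qualifies).
#' @export
froc_operating_point <- function(curve, max_fpv = 4) {
  ok <- curve$fpv <= max_fpv
  if (!any(ok)) return(list(tpr = 0, fpv = NA_real_, threshold = NA_real_))
  best <- which(ok)[which.max(curve$tpr[ok])]
  list(tpr = curve$tpr[best], fpv = curve$fpv[best],
       threshold = curve$threshold[best])
}

#' Summarize per-fold evaluation results
#'
#' @param fold_results list with one element per fold, each a named numeric
#'   vector (e.g. `c(ACC = ..., SEN = ..., SPE = ..., AUC = ..., dice = ...)`).
#' @return `list(per_fold, mean, sd)` where `per_fold` is a data.frame and
#'   `sd` uses the sample (n - 1) formula.
#' @export
crossval_report <- function(fold_results) {
  if (!length(fold_results)) stop("no fold results")
  tab <- do.call(rbind, lapply(fold_results, function(x) as.data.frame(as.list(x))))
  tab <- cbind(fold = seq_len(nrow(tab)), tab)
  mu <- colMeans(tab[-1L])
  sdev <- if (nrow(tab) > 1L) vapply(tab[-1L], sd, numeric(1L)) else
    setNames(rep(0, ncol(tab) - 1L), names(tab)[-1L])
  list(per_fold = tab, mean = mu, sd = sdev)
}
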