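#' f_alpha overlap measure (Dice coefficient at alpha = 1)
#'
#' `f_alpha(S, T) = (1 + alpha^2) * sum(s * t) / (sum(s) + sum(t))`, computed
#' exactly as written over the `M` paired elements of the predicted heatmap
#' `S` (values in `[0, 1]`) and binary ground truth `T`. With `alpha = 1`
#' this is the Dice coefficient.
#'
#' When both `S` and `T` sum to zero the measure is an undefined 0/0; by
#' default this raises an error. Supplying a positive `smooth` adds the
#' smoothing constant to numerator and denominator instead
#' (`((1 + alpha^2) * sum(st) + smooth) / (sum(s) + sum(t) + smooth)`), which
#' is the form used during training so that all-background patches remain
#' differentiable.
#'
#' @param S numeric vector/array of predictions in `[0, 1]`.
#' @param T_ numeric vector/array of 0/1 ground truth, same length.
#' @param alpha class-balance exponent (> 0), default 1.
#' @param smooth smoothing constant (0 = strict formula).
#' @return Scalar overlap score.
#' @export
f_alpha_measure <- function(S, T_, alpha = 1, smooth = 0) {
  if (length(S) == 0L || length(T_) == 0L) stop("empty inputs")
  if (length(S) != length(T_)) stop("S and T must have the same number of elements")
  stopifnot(alpha > 0, smooth >= 0)
  s_sum <- sum(S)
  t_sum <- sum(T_)
  st <- sum(S * T_)
  if (smooth == 0 && s_sum + t_sum == 0) {
    stop("f_alpha undefined: both S and T are all zero (0/0); use smooth > 0")
  }
  ((1 + alpha^2) * st + smooth) / (s_sum + t_sum + smooth)
}

#' Gradient of the f_alpha measure with respect to S
#'
#' @inheritParams f_alpha_measure
#' @return Array shaped like `S` with `d f_alpha / d s_i`.
#' @export
f_alpha_grad <- function(S, T_, alpha = 1, smooth = 0) {
  s_sum <- sum(S)
  t_sum <- sum(T_)
  st <- sum(S * T_)
  denom <- s_sum + t_sum + smooth
  if (denom == 0) stop("f_alpha gradient undefined: zero denominator")
  g <- ((1 + alpha^2) * T_ * denom - ((1 + alpha^2) * st + smooth)) / denom^2
  if (!is.null(dim(S))) dim(g) <- dim(S)
  g
}

#' Training loss: 1 - f_alpha
#'
#' The overlap measure increases with segmentation quality, so the minimized
#' loss is its complement; a perfect prediction scores 0 and a disjoint one
#' scores 1 (at `alpha = 1`).
#'
#' @inheritParams f_alpha_measure
#' @return Non-negative scalar.
#' @export
dice_loss <- function(S, T_, alpha = 1, smooth = 0) {
  1 - f_alpha_measure(S, T_, alpha, smooth)
}

#' Partition volume ids into cross-validation folds
#'
#' Volumes (never patches) are assigned to `k` folds of near-equal size
#' (differing by at most one), deterministically under `seed`.
#'
#' @param volume_ids vector of volume identifiers.
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return List of `k` vectors of test-volume ids (a partition of
#'   `volume_ids`).
#' @export
make_folds <- function(volume_ids, k = 10L, seed = 1L) {
  n <- length(volume_ids)
  if (n < k) stop(sprintf("need at least %d volumes for %d folds, got %d", k, k, n))
  set.seed(seed)
  perm <- sample(volume_ids)
  # deal round-robin so fold sizes differ by <= 1
  unname(split(perm, rep(seq_len(k), length.out = n)))
}

# derive a per-epoch 31-bit seed from the master seed
epoch_seed <- function(master, epoch) {
  as.integer((as.double(master) * 48271 + epoch * 16807) %% 2147483647)
}

adagrad_update <- function(param, grad, state, lr, eps = 1e-8) {
  state <- state + grad * grad
  list(param = param - lr * grad / (sqrt(state) + eps), state = state)
}

patch_batch_array <- function(patches) {
  P <- nrow(patches[[1L]]$pixels)
  B <- length(patches)
  x <- array(0, dim = c(P, P, B, 1L))
  for (i in seq_len(B)) x[, , i, 1L] <- patches[[i]]$pixels
  x
}

patch_batch_truth <- function(patches, mask_list) {
  P <- nrow(patches[[1L]]$pixels)
  B <- length(patches)
  t_arr <- array(0, dim = c(P, P, B))
  for (i in seq_len(B)) {
    p <- patches[[i]]
    m <- mask_list[[p$volume]]$labels[p$slice,
                                      p$origin[1L]:(p$origin[1L] + P - 1L),
                                      p$origin[2L]:(p$origin[2L] + P - 1L)]
    r <- p$rotation %/% 90L
    while (r > 0L) { m <- rotate90(m); r <- r - 1L }
    t_arr[, , i] <- m
  }
  t_arr
}

#' Train the network on a patch source with the f_alpha (Dice) loss
#'
#' Each epoch draws a class-balanced sample of patches, expands it by
#' right-angle rotations (when enabled), shuffles it, and performs Adagrad
#' steps on minibatches under the `1 - f_alpha` loss computed over all
#' pixels of the minibatch. Batch-normalization running statistics are
#' updated each step. Deterministic under the master seed.
#'
#' The patch source is the output of [extract_patches()] over the training
#' volumes, with each patch annotated with its source volume index
#' (`$volume`), plus the list of aligned mask volumes from which dense
#' per-pixel targets are read.
#'
#' @param model a `dbt_net` from [build_network()].
#' @param patches list of `dbt_patch`, each with a `$volume` index.
#' @param masks list of [mask_volume()] indexed by `$volume`.
#' @param cfg a `run_config`; consulted fields: `per_class_n`, `augment`,
#'   `batch_size`, `epochs`, `learning_rate`, `alpha`, `loss_epsilon`,
#'   `seed`.
#' @return `list(model, trace)` with the trained model and the per-epoch
#'   mean-loss trace.
#' @export
train <- function(model, patches, masks, cfg = default_config("desk")) {
  stopifnot(inherits(model, "dbt_net"))
  if (!length(patches)) stop("empty patch source")
  if (is.null(patches[[1L]]$volume)) stop("patches must carry a $volume index")
  lr <- cfg$learning_rate
  state <- lapply(model$layers, function(ly) {
    list(W = array(0, dim = dim(ly$W)), b = numeric(length(ly$b)),
         gamma = if (!is.null(ly$gamma)) numeric(length(ly$gamma)),
         beta = if (!is.null(ly$beta)) numeric(length(ly$beta)))
  })
  trace <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    es <- epoch_seed(cfg$seed, epoch)
    pool <- balanced_epoch_sample(patches, cfg$per_class_n, seed = es)
    if (isTRUE(cfg$augment)) {
      pool <- do.call(c, lapply(pool, augment_rotations))
    }
    set.seed(es + 1L)
    pool <- pool[sample(length(pool))]
    n_batches <- ceiling(length(pool) / cfg$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      idx <- ((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, length(pool))
      batch <- pool[idx]
      x <- patch_batch_array(batch)
      t_arr <- patch_batch_truth(batch, masks)
      fw <- net_forward(model, x, train = TRUE)
      s <- softmax_mass_prob(fw$logits)
      loss <- dice_loss(s, t_arr, cfg$alpha, cfg$loss_epsilon)
      if (!is.finite(loss)) {
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch, bi))
      }
      epoch_loss <- epoch_loss + loss
      # d(loss)/ds -> d/dlogits through the two-class softmax
      gs <- -f_alpha_grad(s, t_arr, cfg$alpha, cfg$loss_epsilon)
      dmass <- gs * s * (1 - s)
      dlogits <- array(0, dim = dim(fw$logits))
      dlogits[, , , 2L] <- dmass
      dlogits[, , , 1L] <- -dmass
      bw <- net_backward(model, fw$cache, dlogits)
      for (li in seq_along(model$layers)) {
        g <- bw$grads[[li]]
        up <- adagrad_update(model$layers[[li]]$W, g$dW, state[[li]]$W, lr)
        model$layers[[li]]$W <- up$param; state[[li]]$W <- up$state
        up <- adagrad_update(model$layers[[li]]$b, g$db, state[[li]]$b, lr)
        model$layers[[li]]$b <- up$param; state[[li]]$b <- up$state
        if (!is.null(g$dgamma)) {
          up <- adagrad_update(model$layers[[li]]$gamma, g$dgamma, state[[li]]$gamma, lr)
          model$layers[[li]]$gamma <- up$param; state[[li]]$gamma <- up$state
          up <- adagrad_update(model$layers[[li]]$beta, g$dbeta, state[[li]]$beta, lr)
          model$layers[[li]]$beta <- up$param; state[[li]]$beta <- up$state
        }
        bn_up <- fw$bn_updates[[li]]
        if (!is.null(bn_up)) {
          model$layers[[li]]$running_mean <- bn_up$running_mean
          model$layers[[li]]$running_var <- bn_up$running_var
        }
      }
      # the forward cache and gradients are large; collect them eagerly so
      # peak memory stays bounded by one batch, not by the GC trigger
      fw <- bw <- x <- t_arr <- s <- gs <- dmass <- dlogits <- NULL
      gc(FALSE)
    }
    trace[epoch] <- epoch_loss / n_batches
  }
  list(model = model, trace = trace)
}
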