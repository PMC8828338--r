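#' d-dilated convolution of a 2D image
#'
#' The literal dilated convolution
#' `(f *_d r)(p) = sum_{s + d t = p} f(s) r(t)` over the kernel support
#' `[-k, k]^2`, with zero padding so the output has the same size as `f`.
#' With `d = 1` this is the ordinary discrete convolution. Note this is true
#' convolution (kernel-flipped relative to cross-correlation).
#'
#' @param f 2D numeric matrix.
#' @param r square kernel of odd side `2k + 1`.
#' @param d dilation factor (>= 1).
#' @return Matrix of the same dimensions as `f`.
#' @export
dilated_conv2d <- function(f, r, d = 1L) {
  stopifnot(is.matrix(f), is.matrix(r))
  if (d < 1) stop("dilation must be >= 1")
  if (nrow(r) %% 2L == 0L || ncol(r) %% 2L == 0L) {
    stop("kernel must have odd spatial extent (2k + 1)")
  }
  dilated_conv2d_cpp(f, r, as.integer(d))
}

#' One layer of the dense-prediction architecture
#'
#' @param kernel spatial kernel side (odd).
#' @param in_ch,out_ch channel counts.
#' @param dilation dilation factor.
#' @param batchnorm apply batch normalization after the convolution.
#' @param activation `"relu"` or `"none"`.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kernel, in_ch, out_ch, dilation = 1L,
                       batchnorm = TRUE, activation = c("relu", "none")) {
  activation <- match.arg(activation)
  stopifnot(kernel %% 2L == 1L, in_ch >= 1, out_ch >= 1, dilation >= 1)
  structure(list(kernel = as.integer(kernel), in_ch = as.integer(in_ch),
                 out_ch = as.integer(out_ch), dilation = as.integer(dilation),
                 batchnorm = isTRUE(batchnorm), activation = activation),
            class = "layer_spec")
}

#' Dense-prediction network architecture
#'
#' The default is the eight-layer dilated fully convolutional architecture:
#' seven 3x3 convolutions (each followed by batch normalization and ReLU)
#' with dilations 1, 1, 2, 4, 8, 16, 1 and 32 channels throughout, then a
#' final 1x1 convolution to 2 output channels with neither batch
#' normalization nor activation. No layer changes the spatial resolution.
#'
#' @param layers list of [layer_spec()]s; consecutive channel counts must
#'   chain, and the final layer must output 2 channels.
#' @param channels channel width used by the default layer stack.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(layers = NULL, channels = 32L) {
  if (is.null(layers)) {
    dil <- c(1L, 1L, 2L, 4L, 8L, 16L, 1L)
    layers <- vector("list", 8L)
    for (i in seq_along(dil)) {
      layers[[i]] <- layer_spec(3L, if (i == 1L) 1L else channels, channels,
                                dilation = dil[i])
    }
    layers[[8L]] <- layer_spec(1L, channels, 2L, dilation = 1L,
                               batchnorm = FALSE, activation = "none")
  }
  for (i in seq_along(layers)[-1L]) {
    if (layers[[i]]$in_ch != layers[[i - 1L]]$out_ch) {
      stop(sprintf("channel mismatch between layer %d (out %d) and layer %d (in %d)",
                   i - 1L, layers[[i - 1L]]$out_ch, i, layers[[i]]$in_ch))
    }
  }
  if (layers[[length(layers)]]$out_ch != 2L) {
    stop("final layer must produce 2 channels (two-class dense prediction)")
  }
  structure(list(layers = layers), class = "architecture_spec")
}

#' Analytic receptive field of an architecture
#'
#' For a stack of square kernels the one-axis receptive field is
#' `1 + sum_i d_i * (kernel_i - 1)`; the default architecture gives
#' `1 + 2 * (1 + 1 + 2 + 4 + 8 + 16 + 1) = 67`.
#'
#' @param spec an [architecture_spec()].
#' @return `c(height, width)`.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  rf <- 1L
  for (ly in spec$layers) rf <- rf + ly$dilation * (ly$kernel - 1L)
  c(height = rf, width = rf)
}

#' Build a network with deterministically initialized weights
#'
#' Convolution weights use He-style initialization
#' (`sd = sqrt(2 / (k^2 * in_ch))`), biases start at zero, batch-norm scale
#' and shift at 1 and 0, running statistics at mean 0 / variance 1. The same
#' seed reproduces bit-identical weights.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed.
#' @return A `dbt_net` model object.
#' @export
build_network <- function(spec = architecture_spec(), seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  layers <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    fan_in <- ly$kernel^2 * ly$in_ch
    W <- array(rnorm(ly$kernel^2 * ly$in_ch * ly$out_ch, sd = sqrt(2 / fan_in)),
               dim = c(ly$kernel, ly$kernel, ly$in_ch, ly$out_ch))
    layers[[i]] <- list(spec = ly, W = W, b = numeric(ly$out_ch),
                        gamma = if (ly$batchnorm) rep(1, ly$out_ch),
                        beta = if (ly$batchnorm) numeric(ly$out_ch),
                        running_mean = if (ly$batchnorm) numeric(ly$out_ch),
                        running_var = if (ly$batchnorm) rep(1, ly$out_ch))
  }
  structure(list(spec = spec, layers = layers, bn_eps = 1e-5,
                 bn_momentum = 0.1, seed = as.integer(seed)),
            class = "dbt_net")
}

#' @export
print.dbt_net <- function(x, ...) {
  cat(sprintf("<dbt_net> %d layers, receptive field %d x %d\n",
              length(x$layers), receptive_field(x$spec)[1L],
              receptive_field(x$spec)[2L]))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]$spec
    cat(sprintf("  %d: %dx%dx%dx%d d=%d%s%s\n", i, ly$kernel, ly$kernel,
                ly$in_ch, ly$out_ch, ly$dilation,
                if (ly$batchnorm) " +bn" else "",
                if (ly$activation == "relu") " +relu" else ""))
  }
  invisible(x)
}

# per-channel statistics of an (H, W, B, C) activation
channel_matrix <- function(x) matrix(x, ncol = dim(x)[4L])

bn_forward <- function(x, layer, eps, train) {
  C <- dim(x)[4L]
  xm <- channel_matrix(x)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu, `-`)
    v <- colMeans(xc * xc)   # biased variance, as standard for batch norm
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
    xc <- sweep(xm, 2L, mu, `-`)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  y <- sweep(sweep(xhat, 2L, layer$gamma, `*`), 2L, layer$beta, `+`)
  dim(y) <- dim(x)
  list(y = y, xhat = xhat, mu = mu, var = v, invstd = invstd)
}

bn_backward <- function(dy, cache, gamma) {
  dym <- channel_matrix(dy)
  N <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2L, gamma, `*`)
  sum_dxhat <- colSums(dxhat)
  sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2L, sum_dxhat / N, `-`) -
    sweep(cache$xhat, 2L, sum_dxhat_xhat / N, `*`)
  dx <- sweep(dx, 2L, cache$invstd, `*`)
  dim(dx) <- dim(dy)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

#' Forward pass of the network
#'
#' @param model a `dbt_net`.
#' @param x input activation array `(H, W, B, C_in)`.
#' @param train use batch statistics (and cache intermediates for
#'   [net_backward()]); otherwise running statistics.
#' @return `list(logits, cache, bn_updates)`; `logits` is `(H, W, B, 2)`.
#'   `bn_updates` holds refreshed running statistics when `train = TRUE`.
#' @export
net_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "dbt_net"), length(dim(x)) == 4L)
  cache <- vector("list", length(model$layers))
  bn_updates <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    z <- conv_fwd_cpp(x, ly$W, ly$b, ly$spec$dilation)
    # intermediates are retained only when a backward pass will need them
    entry <- if (train) list(x_in = x) else NULL
    h <- z
    if (ly$spec$batchnorm) {
      bn <- bn_forward(z, ly, model$bn_eps, train)
      h <- bn$y
      if (train) {
        entry$bn <- bn[c("xhat", "mu", "var", "invstd")]
        m <- model$bn_momentum
        bn_updates[[i]] <- list(
          running_mean = (1 - m) * ly$running_mean + m * bn$mu,
          running_var = (1 - m) * ly$running_var + m * bn$var)
      }
      bn <- NULL
    }
    z <- NULL
    if (ly$spec$activation == "relu") {
      if (train) entry$pre_relu <- h
      h <- h * (h > 0)
    }
    if (train) cache[[i]] <- entry
    x <- h
  }
  list(logits = x, cache = if (train) cache else NULL, bn_updates = bn_updates)
}

#' Backward pass of the network
#'
#' @param model a `dbt_net`.
#' @param cache forward cache from `net_forward(..., train = TRUE)`.
#' @param dlogits gradient of the loss w.r.t. the logits, `(H, W, B, 2)`.
#' @return `list(grads, dx)`: per-layer gradients (`dW`, `db`, `dgamma`,
#'   `dbeta`) and the gradient w.r.t. the network input.
#' @export
net_backward <- function(model, cache, dlogits) {
  grads <- vector("list", length(model$layers))
  dy <- dlogits
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    entry <- cache[[i]]
    if (ly$spec$activation == "relu") {
      dy <- dy * (entry$pre_relu > 0)
    }
    g <- list()
    if (ly$spec$batchnorm) {
      bnb <- bn_backward(dy, entry$bn, ly$gamma)
      dy <- bnb$dx
      g$dgamma <- bnb$dgamma
      g$dbeta <- bnb$dbeta
    }
    cb <- conv_bwd_cpp(entry$x_in, ly$W, dy, ly$spec$dilation)
    g$dW <- cb$dW
    g$db <- cb$db
    grads[[i]] <- g
    dy <- cb$dX
  }
  list(grads = grads, dx = dy)
}

# two-class softmax probability of the mass channel, numerically stable
softmax_mass_prob <- function(logits) {
  H <- dim(logits)[1L]; W <- dim(logits)[2L]; B <- dim(logits)[3L]
  p <- plogis(logits[, , , 2L, drop = FALSE] - logits[, , , 1L, drop = FALSE])
  array(p, dim = c(H, W, B))
}

#' Dense per-pixel mass-probability prediction for a volume
#'
#' Runs the network on every slice independently (evaluation-mode batch
#' normalization) and applies a two-class softmax, returning the
#' mass-channel probability at every voxel.
#'
#' @param model a `dbt_net`.
#' @param vol an [image_volume()] (typically preprocessed).
#' @return A `heatmap` object: `list(probabilities)` with a 3D array in
#'   `[0, 1]` of the same shape as the volume.
#' @export
predict_heatmap <- function(model, vol) {
  stopifnot(inherits(model, "dbt_net"), inherits(vol, "image_volume"))
  d <- dim(vol$voxels)
  probs <- array(0, dim = d)
  for (s in seq_len(d[1L])) {
    x <- array(vol$voxels[s, , ], dim = c(d[2L], d[3L], 1L, 1L))
    fw <- net_forward(model, x, train = FALSE)
    probs[s, , ] <- softmax_mass_prob(fw$logits)[, , 1L]
  }
  heatmap_volume(probs)
}

#' Heatmap container
#'
#' A dense per-voxel class-probability map aligned to its source volume.
#'
#' @param probabilities 3D array with values in `[0, 1]`.
#' @return An object of class `heatmap`.
#' @export
heatmap_volume <- function(probabilities) {
  if (length(dim(probabilities)) == 2L) {
    probabilities <- array(probabilities, dim = c(1L, dim(probabilities)))
  }
  stopifnot(length(dim(probabilities)) == 3L,
            min(probabilities) >= 0, max(probabilities) <= 1)
  structure(list(probabilities = probabilities), class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  d <- dim(x$probabilities)
  cat(sprintf("<heatmap> %d x %d x %d, mean p = %.4f\n",
              d[1L], d[2L], d[3L], mean(x$probabilities)))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is written with R's native serialization, next to a YAML
#' sidecar (`<path>.yaml`) recording the architecture and seed for
#' provenance.
#'
#' @param model a `dbt_net`.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `path` (for `save_model`) or the restored `dbt_net`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dbt_net"))
  saveRDS(model, path)
  side <- lapply(model$spec$layers, function(ly) {
    list(kernel = ly$kernel, in_ch = ly$in_ch, out_ch = ly$out_ch,
         dilation = ly$dilation, batchnorm = ly$batchnorm,
         activation = ly$activation)
  })
  yaml::write_yaml(list(seed = model$seed, layers = side),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "dbt_net")) stop("not a dbt_net checkpoint")
  model
}
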