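# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementations.

# literal nested-sum dilated convolution: (f *_d r)(p) = sum_{s + d t = p} f(s) r(t)
oracle_dilated_conv <- function(f, r, d) {
  k <- (nrow(r) - 1L) / 2L
  H <- nrow(f); W <- ncol(f)
  out <- matrix(0, H, W)
  for (p1 in seq_len(H)) {
    for (p2 in seq_len(W)) {
      acc <- 0
      for (t1 in -k:k) {
        for (t2 in -k:k) {
          s1 <- p1 - d * t1
          s2 <- p2 - d * t2
          if (s1 >= 1 && s1 <= H && s2 >= 1 && s2 <= W) {
            acc <- acc + f[s1, s2] * r[t1 + k + 1L, t2 + k + 1L]
          }
        }
      }
      out[p1, p2] <- acc
    }
  }
  out
}

# exhaustive sliding-window origin enumeration (1-based, row-major)
oracle_origins <- function(height, width, patch_size, stride) {
  out <- NULL
  r <- 1L
  while (r + patch_size - 1L <= height) {
    c_ <- 1L
    while (c_ + patch_size - 1L <= width) {
      out <- rbind(out, c(r, c_))
      c_ <- c_ + stride
    }
    r <- r + stride
  }
  out
}

# recursive-free flood-fill 3D connected-component labelling
oracle_label <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18L) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (i in which(mask == 1L & lab == 0L)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ai <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- ai + as.integer(offs[o, ])
        if (any(p < 1L) || any(p > d)) next
        j <- p[1L] + d[1L] * ((p[2L] - 1L) + d[2L] * (p[3L] - 1L))
        if (mask[j] == 1L && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# Mann-Whitney rank-statistic AUC
oracle_rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# tiny phantom population used for fast module-level tests
tiny_phantom_spec <- function(seed = 1L, n_lesions = 1L) {
  phantom_spec(shape = c(8L, 64L, 64L), n_lesions = n_lesions,
               diameter_range_mm = c(1.5, 3), seed = seed)
}
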