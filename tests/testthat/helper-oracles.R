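# Independent brute-force oracles. These deliberately use naive nested
# loops / all-pairs enumeration so they share no code path with the
# package implementations they check.

# naive same-padded 3x3 convolution; x: H x W x Cin array,
# kern: 3 x 3 x Cin x Cout, bias: length Cout
oracle_conv3x3 <- function(x, kern, bias) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]; Cout <- dim(kern)[4]
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) {
    for (r in seq_len(H)) for (c in seq_len(W)) {
      acc <- bias[co]
      for (i in 1:3) for (j in 1:3) {
        rr <- r + i - 2; cc <- c + j - 2
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          for (ci in seq_len(Cin)) acc <- acc + x[rr, cc, ci] * kern[i, j, ci, co]
        }
      }
      out[r, c, co] <- acc
    }
  }
  out
}

# naive window pooling; x: H x W matrix, f: factor, fun: max or mean
oracle_pool <- function(x, f, fun) {
  H <- nrow(x) / f; W <- ncol(x) / f
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    out[r, c] <- fun(x[((r - 1) * f + 1):(r * f), ((c - 1) * f + 1):(c * f)])
  }
  out
}

oracle_upsample <- function(x, f) {
  out <- matrix(0, nrow(x) * f, ncol(x) * f)
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    out[r, c] <- x[ceiling(r / f), ceiling(c / f)]
  }
  out
}

oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] == 1 && truth[k] == 1) tp <- tp + 1L
    if (pred[k] == 1 && truth[k] == 0) fp <- fp + 1L
    if (pred[k] == 0 && truth[k] == 0) tn <- tn + 1L
    if (pred[k] == 0 && truth[k] == 1) fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_dsc <- function(pred, truth) {
  a <- which(pred == 1); b <- which(truth == 1)
  if (length(a) + length(b) == 0) return(1.0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Mann-Whitney rank statistic over all positive/negative pairs (ties 1/2)
oracle_auc <- function(probs, truth) {
  pos <- probs[truth == 1]; neg <- probs[truth == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# boundary pixels by definition: foreground with a background 4-neighbour
# (border counts as background)
oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pts <- NULL
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (mask[r, c] != 1) next
    nb <- c(
      if (r > 1) mask[r - 1, c] else 0, if (r < H) mask[r + 1, c] else 0,
      if (c > 1) mask[r, c - 1] else 0, if (c < W) mask[r, c + 1] else 0)
    if (any(nb == 0) || r == 1 || r == H || c == 1 || c == W) {
      pts <- rbind(pts, c(r, c))
    }
  }
  pts
}

# all-pairs directed percentile Hausdorff
oracle_hd95 <- function(pred, truth, percentile = 0.95) {
  a <- oracle_boundary(pred); b <- oracle_boundary(truth)
  dmat <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    dmat[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  }
  d_ab <- apply(dmat, 1, min)
  d_ba <- apply(dmat, 2, min)
  max(quantile(d_ab, percentile, names = FALSE),
      quantile(d_ba, percentile, names = FALSE))
}

# recursive flood fill component labeling
oracle_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nbrs <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  k <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (mask[r0, c0] != 1 || lab[r0, c0] != 0) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nbrs))) {
        q <- p + nbrs[i, ]
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- k
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

random_mask <- function(n, p = 0.3) {
  matrix(rbinom(n * n, 1, p), n, n)
}

# tiny preprocessed phantom training set shared across tests
make_micro_pairs <- function(n_patients = 4, slices = 2, image_size = 64, seed = 11) {
  spec <- phantom_spec(image_size = image_size, seed = seed)
  ds <- generate_dataset(spec, n_patients = n_patients, slices_per_patient = slices)
  pipe <- build_pipeline(preprocess_cfg(target_size = image_size, equalize = "off",
                                        denoise = "off", augment = character(0)))
  list(pairs = lapply(ds$pairs, pipe), manifest = ds$manifest)
}
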