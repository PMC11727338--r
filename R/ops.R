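# R-side wrappers around the compiled tensor kernels.
#
# A feature map is a plain (H*W) x C double matrix; pixel p = r + (c-1)*H in
# 1-based terms (column-major over the image grid). Helpers here convert
# between H x W (x C) arrays and that layout, and hold the parameter
# containers for convolution layers.

# ---- layout -----------------------------------------------------------------

# H x W matrix or H x W x C array -> (H*W) x C matrix plus dims.
as_featuremap <- function(x) {
  d <- dim(x)
  if (length(d) == 2) {
    list(x = matrix(as.double(x), ncol = 1L), H = d[1], W = d[2])
  } else if (length(d) == 3) {
    list(x = matrix(as.double(x), nrow = d[1] * d[2], ncol = d[3]),
         H = d[1], W = d[2])
  } else {
    stop("expected a 2-D or 3-D array", call. = FALSE)
  }
}

# (H*W) x C matrix -> H x W (C == 1) or H x W x C array.
from_featuremap <- function(x, H, W) {
  if (ncol(x) == 1L) matrix(x, H, W) else array(x, dim = c(H, W, ncol(x)))
}

# ---- primitive layers -------------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid_act <- function(x) 1 / (1 + exp(-x))

conv1x1_fwd <- function(x, W, b) sweep(x %*% W, 2L, b, "+")

upsample_nearest <- function(x, H, W, f) cpp_upsample_nearest(x, H, W, f)

avgpool_fwd <- function(x, H, W, f) cpp_sumpool(x, H, W, f) / (f * f)

# Adjoint of avgpool: spread the gradient evenly over each f x f block.
avgpool_bwd <- function(dy, Ho, Wo, f) cpp_upsample_nearest(dy, Ho, Wo, f) / (f * f)

# ---- parameter containers ---------------------------------------------------

# He-uniform initialisation for a k x k convolution, stored in the row
# layout the C++ kernels expect (off*C_in + ch; see src/ops.cpp).
init_conv <- function(c_in, c_out, k = 3L) {
  fan_in <- k * k * c_in
  limit <- sqrt(6 / fan_in)
  list(W = matrix(runif(k * k * c_in * c_out, -limit, limit), k * k * c_in, c_out),
       b = numeric(c_out))
}

#' Pack a 3x3 kernel array into the internal weight-matrix layout
#'
#' Converts a `3 x 3 x c_in x c_out` kernel array (first index = row offset,
#' second = column offset) into the `(9*c_in) x c_out` matrix used by the
#' convolution kernels. Mainly useful for setting weights by hand in tests
#' and demonstrations.
#'
#' @param k A `3 x 3 x c_in x c_out` numeric array.
#' @return A `(9*c_in) x c_out` matrix.
#' @export
kernel_to_matrix <- function(k) {
  stopifnot(length(dim(k)) == 4, dim(k)[1] == 3, dim(k)[2] == 3)
  c_in <- dim(k)[3]; c_out <- dim(k)[4]
  W <- matrix(0, 9 * c_in, c_out)
  for (i in 1:3) for (j in 1:3) for (ch in seq_len(c_in)) {
    off <- (i - 1) + (j - 1) * 3
    W[off * c_in + ch, ] <- k[i, j, ch, ]
  }
  W
}

# ---- composite blocks (forward + hand-derived backward) ---------------------

# Triple 3x3 convolution block, each conv followed by ReLU (channel plan
# c_in -> c_out -> c_out -> c_out). Optional residual add of the first
# activation onto the last (off by default; the tables draw no residual path).
conv_block_fwd <- function(p, prefix, x, H, W, residual = FALSE, keep = FALSE) {
  a1 <- cpp_conv3x3_fwd(x,  H, W, p[[paste0(prefix, "_c1_W")]], p[[paste0(prefix, "_c1_b")]])
  r1 <- relu(a1)
  a2 <- cpp_conv3x3_fwd(r1, H, W, p[[paste0(prefix, "_c2_W")]], p[[paste0(prefix, "_c2_b")]])
  r2 <- relu(a2)
  a3 <- cpp_conv3x3_fwd(r2, H, W, p[[paste0(prefix, "_c3_W")]], p[[paste0(prefix, "_c3_b")]])
  if (residual) a3 <- a3 + r1
  r3 <- relu(a3)
  cache <- if (keep) list(x = x, r1 = r1, r2 = r2, out = r3,
                          m1 = a1 > 0, m2 = a2 > 0, m3 = a3 > 0) else NULL
  list(out = r3, cache = cache)
}

conv_block_bwd <- function(p, prefix, cache, dout, H, W, residual = FALSE) {
  g <- list()
  d3 <- dout * cache$m3
  b3 <- cpp_conv3x3_bwd(cache$r2, H, W, p[[paste0(prefix, "_c3_W")]], d3)
  g[[paste0(prefix, "_c3_W")]] <- b3$dW; g[[paste0(prefix, "_c3_b")]] <- as.numeric(b3$db)
  d2 <- b3$dX * cache$m2
  b2 <- cpp_conv3x3_bwd(cache$r1, H, W, p[[paste0(prefix, "_c2_W")]], d2)
  g[[paste0(prefix, "_c2_W")]] <- b2$dW; g[[paste0(prefix, "_c2_b")]] <- as.numeric(b2$db)
  dr1 <- b2$dX
  if (residual) dr1 <- dr1 + d3
  d1 <- dr1 * cache$m1
  b1 <- cpp_conv3x3_bwd(cache$x, H, W, p[[paste0(prefix, "_c1_W")]], d1)
  g[[paste0(prefix, "_c1_W")]] <- b1$dW; g[[paste0(prefix, "_c1_b")]] <- as.numeric(b1$db)
  list(dx = b1$dX, grads = g)
}

# Spatial attention block: gate = sigmoid(1x1 conv over concat[avgpool,
# maxpool]), value = 1x1 conv of the max-pooled map (C -> 2C); output is the
# elementwise product. Pool factor f halves (f = 2) the spatial dims.
# `gate_mode = "open"` forces the gate to 1 (ablation hook).
attn_block_fwd <- function(p, prefix, x, H, W, f = 2L, gate_mode = "learned", keep = FALSE) {
  mp <- cpp_maxpool_fwd(x, H, W, f)
  ap <- avgpool_fwd(x, H, W, f)
  g_in <- cbind(ap, mp$out)
  z <- conv1x1_fwd(g_in, p[[paste0(prefix, "_gate_W")]], p[[paste0(prefix, "_gate_b")]])
  gate <- if (identical(gate_mode, "open")) matrix(1, nrow(z), ncol(z)) else sigmoid_act(z)
  v <- conv1x1_fwd(mp$out, p[[paste0(prefix, "_val_W")]], p[[paste0(prefix, "_val_b")]])
  out <- gate * v
  cache <- if (keep) list(mp = mp, g_in = g_in, gate = gate, v = v, HW = H * W,
                          f = f, gate_mode = gate_mode) else NULL
  list(out = out, gate = gate, cache = cache)
}

attn_block_bwd <- function(p, prefix, cache, dout, Ho, Wo) {
  g <- list()
  dgate <- dout * cache$v
  dv <- dout * cache$gate
  # value path (1x1 conv of max-pooled input)
  g[[paste0(prefix, "_val_W")]] <- crossprod(cache$mp$out, dv)
  g[[paste0(prefix, "_val_b")]] <- colSums(dv)
  dmp <- dv %*% t(p[[paste0(prefix, "_val_W")]])
  # gate path
  if (identical(cache$gate_mode, "open")) {
    dz <- matrix(0, nrow(dgate), ncol(dgate))
  } else {
    dz <- dgate * cache$gate * (1 - cache$gate)
  }
  g[[paste0(prefix, "_gate_W")]] <- crossprod(cache$g_in, dz)
  g[[paste0(prefix, "_gate_b")]] <- colSums(dz)
  dg_in <- dz %*% t(p[[paste0(prefix, "_gate_W")]])
  C <- ncol(cache$mp$out)
  dap <- dg_in[, seq_len(C), drop = FALSE]
  dmp <- dmp + dg_in[, C + seq_len(C), drop = FALSE]
  dx <- cpp_maxpool_bwd(dmp, cache$mp$idx, cache$HW) +
    avgpool_bwd(dap, Ho, Wo, cache$f)
  list(dx = dx, grads = g)
}
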