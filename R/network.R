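# The spatial-attention U-Net.
#
# Encoder: FP1 (3->16 conv block) -> FSA1 (attention, 16->32, /2)
#          -> FP2 (32->32 conv block, maxpool /4) -> FP3 (32->64 conv block)
#          -> FSA2 (attention, 64->128, /2) -> FP4 (128->128 conv block,
#          maxpool /4) -> FP5 bottleneck (128->256 conv block).
# Decoder: four upsample(+concat skip)+conv-block stages with factors
#          [4, 2, 4, 2] landing on the stored skips [FSA2, FP3, FSA1, FP1]
#          (channels 256->128->64->32->16), then a 3x3 output head and a
#          pixel-wise sigmoid. Total down factor 2*4*2*4 = 64 equals the
#          total up factor, so output spatial dims equal input dims.
#
# Each attention block doubles the channels: its gate is a sigmoid-activated
# 1x1 convolution over the channel-concat of the average-pooled and
# max-pooled input (2C -> 2C), its value path a 1x1 convolution of the
# max-pooled input (C -> 2C), combined by elementwise product.

#' Network configuration
#'
#' The default layer plan uses encoder widths 16, 32, 32, 64, 128, 128, 256
#' (FP1, FSA1, FP2, FP3, FSA2, FP4, bottleneck), attention after FP1 and
#' FP3, encoder pool factors `c(2, 4, 2, 4)` and decoder upsample factors
#' `c(4, 2, 4, 2)`. `width_multiplier` scales every width (minimum 1
#' channel) for desk-scale training and tests.
#'
#' @param in_channels Input image channels (default 3; grayscale inputs are
#'   replicated).
#' @param base_width Channels of the first conv block (default 16).
#' @param width_multiplier Scale factor applied to all widths.
#' @param out_channels Output channels (default 1 for binary
#'   sigmoid/BCE; set 3 to mirror the printed 3-channel head).
#' @param attention_gates `"learned"` (sigmoid gates) or `"open"` (gates
#'   forced to 1 — ablation that reduces the model to a plain conv encoder).
#' @param residual If `TRUE`, conv blocks add their first activation onto
#'   their last pre-activation (off by default; the layer plan draws none).
#' @return A `network_cfg` object.
#' @export
network_cfg <- function(in_channels = 3L,
                        base_width = 16L,
                        width_multiplier = 1,
                        out_channels = 1L,
                        attention_gates = c("learned", "open"),
                        residual = FALSE) {
  attention_gates <- match.arg(attention_gates)
  if (out_channels < 1) stop("out_channels must be >= 1", call. = FALSE)
  w <- function(k) max(1L, as.integer(round(k * (base_width / 16) * width_multiplier)))
  widths <- c(fp1 = w(16), fsa1 = w(32), fp2 = w(32), fp3 = w(64),
              fsa2 = w(128), fp4 = w(128), fp5 = w(256))
  pool_factors <- c(2L, 4L, 2L, 4L)
  upsample_factors <- c(4L, 2L, 4L, 2L)
  stopifnot(prod(pool_factors) == prod(upsample_factors))
  structure(list(in_channels = as.integer(in_channels),
                 base_width = as.integer(base_width),
                 width_multiplier = width_multiplier,
                 widths = widths,
                 pool_factors = pool_factors,
                 upsample_factors = upsample_factors,
                 attn_pool = 2L,
                 out_channels = as.integer(out_channels),
                 attention_gates = attention_gates,
                 residual = residual,
                 down_factor = prod(pool_factors)),
            class = "network_cfg")
}

conv_block_params <- function(prefix, c_in, c_out) {
  p <- list()
  cs <- c(c_in, c_out, c_out)
  for (i in 1:3) {
    cv <- init_conv(cs[i], c_out, 3L)
    p[[paste0(prefix, "_c", i, "_W")]] <- cv$W
    p[[paste0(prefix, "_c", i, "_b")]] <- cv$b
  }
  p
}

attn_block_params <- function(prefix, c_in) {
  gate <- init_conv(2L * c_in, 2L * c_in, 1L)
  val <- init_conv(c_in, 2L * c_in, 1L)
  p <- list()
  p[[paste0(prefix, "_gate_W")]] <- gate$W
  p[[paste0(prefix, "_gate_b")]] <- gate$b
  p[[paste0(prefix, "_val_W")]] <- val$W
  p[[paste0(prefix, "_val_b")]] <- val$b
  p
}

#' Build a spatial-attention U-Net with seeded He-uniform weights
#'
#' @param cfg A [network_cfg()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `sa_unet` holding `cfg` and the named
#'   parameter list.
#' @export
sa_unet <- function(cfg = network_cfg(), seed = 1L) {
  w <- cfg$widths
  with_seed(seed, {
    p <- c(
      conv_block_params("enc1", cfg$in_channels, w["fp1"]),
      attn_block_params("att1", w["fp1"]),
      conv_block_params("enc2", w["fsa1"], w["fp2"]),
      conv_block_params("enc3", w["fp2"], w["fp3"]),
      attn_block_params("att2", w["fp3"]),
      conv_block_params("enc4", w["fsa2"], w["fp4"]),
      conv_block_params("bott", w["fp4"], w["fp5"]),
      conv_block_params("dec1", w["fp5"] + w["fsa2"], w["fp4"]),
      conv_block_params("dec2", w["fp4"] + w["fp3"], w["fp3"]),
      conv_block_params("dec3", w["fp3"] + w["fsa1"], w["fsa1"]),
      conv_block_params("dec4", w["fsa1"] + w["fp1"], w["fp1"])
    )
    head <- init_conv(w["fp1"], cfg$out_channels, 3L)
    p[["head_W"]] <- head$W
    p[["head_b"]] <- head$b
    structure(list(cfg = cfg, params = p, seed = as.integer(seed)),
              class = "sa_unet")
  })
}

#' Number of trainable parameters
#' @param model An `sa_unet`.
#' @return Integer count of all weights and biases.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

check_input_dims <- function(cfg, H, W) {
  f <- cfg$down_factor
  if (H %% f != 0 || W %% f != 0) {
    stop(sprintf("input spatial dims must be divisible by %d (got %dx%d)", f, H, W),
         call. = FALSE)
  }
}

prepare_input <- function(model, x) {
  fm <- as_featuremap(x)
  if (ncol(fm$x) == 1L && model$cfg$in_channels > 1L) {
    # grayscale replicated across the expected input channels
    fm$x <- fm$x[, rep(1L, model$cfg$in_channels), drop = FALSE]
  }
  if (ncol(fm$x) != model$cfg$in_channels) {
    stop(sprintf("input has %d channels, network expects %d",
                 ncol(fm$x), model$cfg$in_channels), call. = FALSE)
  }
  check_input_dims(model$cfg, fm$H, fm$W)
  fm
}

#' Run the encoder: conv/attention blocks down to the bottleneck input
#'
#' @param model An `sa_unet`.
#' @param x Image as `H x W` matrix or `H x W x C` array, dims divisible
#'   by 64.
#' @return List with `bottleneck_in` (the pooled FP4 feature map as an
#'   `H x W x C` array) and `skips`, the ordered encoder maps
#'   `list(FP1, FSA1, FP3, FSA2)`.
#' @export
encoder_forward <- function(model, x) {
  fm <- prepare_input(model, x)
  fwd <- unet_forward_internal(model, fm, keep = FALSE, encoder_only = TRUE)
  list(bottleneck_in = from_featuremap(fwd$p4, fwd$dims$bott[1], fwd$dims$bott[2]),
       skips = list(
         FP1 = from_featuremap(fwd$fp1, fwd$dims$s0[1], fwd$dims$s0[2]),
         FSA1 = from_featuremap(fwd$fsa1, fwd$dims$s1[1], fwd$dims$s1[2]),
         FP3 = from_featuremap(fwd$fp3, fwd$dims$s2[1], fwd$dims$s2[2]),
         FSA2 = from_featuremap(fwd$fsa2, fwd$dims$s3[1], fwd$dims$s3[2])))
}

# Shared forward pass over featuremap matrices. Returns all intermediates
# needed for the decoder and (in training) the caches for backprop.
unet_forward_internal <- function(model, fm, keep = FALSE, encoder_only = FALSE,
                                  gate_mode = NULL) {
  p <- model$params
  cfg <- model$cfg
  gate_mode <- gate_mode %||% cfg$attention_gates
  res <- cfg$residual
  H <- fm$H; W <- fm$W
  dims <- list(s0 = c(H, W))

  b1 <- conv_block_fwd(p, "enc1", fm$x, H, W, res, keep)                    # FP1 @ s0
  a1 <- attn_block_fwd(p, "att1", b1$out, H, W, cfg$attn_pool, gate_mode, keep)
  H1 <- H / 2L; W1 <- W / 2L; dims$s1 <- c(H1, W1)                          # FSA1 @ s0/2
  b2 <- conv_block_fwd(p, "enc2", a1$out, H1, W1, res, keep)                # FP2 conv @ s0/2
  mp2 <- cpp_maxpool_fwd(b2$out, H1, W1, cfg$pool_factors[2])
  H2 <- H1 / 4L; W2 <- W1 / 4L; dims$s2 <- c(H2, W2)                        # FP2 @ s0/8
  b3 <- conv_block_fwd(p, "enc3", mp2$out, H2, W2, res, keep)               # FP3 @ s0/8
  a2 <- attn_block_fwd(p, "att2", b3$out, H2, W2, cfg$attn_pool, gate_mode, keep)
  H3 <- H2 / 2L; W3 <- W2 / 2L; dims$s3 <- c(H3, W3)                        # FSA2 @ s0/16
  b4 <- conv_block_fwd(p, "enc4", a2$out, H3, W3, res, keep)                # FP4 conv @ s0/16
  mp4 <- cpp_maxpool_fwd(b4$out, H3, W3, cfg$pool_factors[4])
  H4 <- H3 / 4L; W4 <- W3 / 4L; dims$bott <- c(H4, W4)                      # FP4 @ s0/64

  out <- list(fp1 = b1$out, fsa1 = a1$out, fp3 = b3$out, fsa2 = a2$out,
              p4 = mp4$out, dims = dims,
              gates = list(att1 = a1$gate, att2 = a2$gate))
  if (keep) out$caches <- list(b1 = b1$cache, a1 = a1$cache, b2 = b2$cache,
                               mp2 = mp2, b3 = b3$cache, a2 = a2$cache,
                               b4 = b4$cache, mp4 = mp4)
  if (encoder_only) return(out)

  b5 <- conv_block_fwd(p, "bott", mp4$out, H4, W4, res, keep)               # FP5 @ s0/64

  up <- cfg$upsample_factors
  u1 <- cpp_upsample_nearest(b5$out, H4, W4, up[1])                         # -> s0/16
  d1 <- conv_block_fwd(p, "dec1", cbind(u1, a2$out), H3, W3, res, keep)
  u2 <- cpp_upsample_nearest(d1$out, H3, W3, up[2])                         # -> s0/8
  d2 <- conv_block_fwd(p, "dec2", cbind(u2, b3$out), H2, W2, res, keep)
  u3 <- cpp_upsample_nearest(d2$out, H2, W2, up[3])                         # -> s0/2
  d3 <- conv_block_fwd(p, "dec3", cbind(u3, a1$out), H1, W1, res, keep)
  u4 <- cpp_upsample_nearest(d3$out, H1, W1, up[4])                         # -> s0
  d4 <- conv_block_fwd(p, "dec4", cbind(u4, b1$out), H, W, res, keep)
  logits <- cpp_conv3x3_fwd(d4$out, H, W, p$head_W, p$head_b)
  probs <- sigmoid_act(logits)

  out$probs <- probs
  out$logits <- logits
  if (keep) out$caches <- c(out$caches,
                            list(b5 = b5$cache, d1 = d1$cache, d2 = d2$cache,
                                 d3 = d3$cache, d4 = d4$cache))
  out
}

# Backward pass given d(loss)/d(logits); returns gradients for every
# parameter, in the same named layout as model$params.
unet_backward_internal <- function(model, fwd, dlogits) {
  p <- model$params
  cfg <- model$cfg
  res <- cfg$residual
  w <- cfg$widths
  ca <- fwd$caches
  dims <- fwd$dims
  H <- dims$s0[1]; W <- dims$s0[2]
  H1 <- dims$s1[1]; W1 <- dims$s1[2]
  H2 <- dims$s2[1]; W2 <- dims$s2[2]
  H3 <- dims$s3[1]; W3 <- dims$s3[2]
  up <- cfg$upsample_factors
  split_cols <- function(m, n_first) {
    list(m[, seq_len(n_first), drop = FALSE],
         m[, n_first + seq_len(ncol(m) - n_first), drop = FALSE])
  }

  # output head
  bh <- cpp_conv3x3_bwd(ca$d4$out, H, W, p$head_W, dlogits)
  g <- list(head_W = bh$dW, head_b = as.numeric(bh$db))

  # decoder (reverse order); each block's input gradient splits into the
  # upsampled path (back through sum-pooling, the adjoint of nearest
  # upsampling) and the skip path
  bd4 <- conv_block_bwd(p, "dec4", ca$d4, bh$dX, H, W, res)
  g <- c(g, bd4$grads)
  s4 <- split_cols(bd4$dx, w[["fsa1"]])
  dfp1_skip <- s4[[2]]
  bd3 <- conv_block_bwd(p, "dec3", ca$d3, cpp_sumpool(s4[[1]], H, W, up[4]), H1, W1, res)
  g <- c(g, bd3$grads)
  s3 <- split_cols(bd3$dx, w[["fp3"]])
  dfsa1_skip <- s3[[2]]
  bd2 <- conv_block_bwd(p, "dec2", ca$d2, cpp_sumpool(s3[[1]], H1, W1, up[3]), H2, W2, res)
  g <- c(g, bd2$grads)
  s2 <- split_cols(bd2$dx, w[["fp4"]])
  dfp3_skip <- s2[[2]]
  bd1 <- conv_block_bwd(p, "dec1", ca$d1, cpp_sumpool(s2[[1]], H2, W2, up[2]), H3, W3, res)
  g <- c(g, bd1$grads)
  s1 <- split_cols(bd1$dx, w[["fp5"]])
  dfsa2_skip <- s1[[2]]

  # bottleneck
  bb5 <- conv_block_bwd(p, "bott", ca$b5, cpp_sumpool(s1[[1]], H3, W3, up[1]),
                        dims$bott[1], dims$bott[2], res)
  g <- c(g, bb5$grads)

  # encoder (reverse order), merging decoder skip gradients
  bb4 <- conv_block_bwd(p, "enc4", ca$b4,
                        cpp_maxpool_bwd(bb5$dx, ca$mp4$idx, H3 * W3), H3, W3, res)
  g <- c(g, bb4$grads)
  ba2 <- attn_block_bwd(p, "att2", ca$a2, bb4$dx + dfsa2_skip, H3, W3)
  g <- c(g, ba2$grads)
  bb3 <- conv_block_bwd(p, "enc3", ca$b3, ba2$dx + dfp3_skip, H2, W2, res)
  g <- c(g, bb3$grads)
  bb2 <- conv_block_bwd(p, "enc2", ca$b2,
                        cpp_maxpool_bwd(bb3$dx, ca$mp2$idx, H1 * W1), H1, W1, res)
  g <- c(g, bb2$grads)
  ba1 <- attn_block_bwd(p, "att1", ca$a1, bb2$dx + dfsa1_skip, H1, W1)
  g <- c(g, ba1$grads)
  bb1 <- conv_block_bwd(p, "enc1", ca$b1, ba1$dx + dfp1_skip, H, W, res)
  g <- c(g, bb1$grads)
  g
}

#' Forward pass: probability map for an input image
#'
#' Runs the full encoder-attention-decoder network and the sigmoid output
#' head. All returned values lie strictly in (0, 1).
#'
#' @param model An `sa_unet`.
#' @param x Image as `H x W` matrix or `H x W x C` array; spatial dims must
#'   be divisible by 64. Grayscale inputs are replicated to the expected
#'   channel count.
#' @param gates Override for the attention gates: `NULL` (use the model
#'   config), `"learned"`, or `"open"` (force gates to 1).
#' @return `H x W` probability matrix (or `H x W x out_channels` array).
#' @export
unet_forward <- function(model, x, gates = NULL) {
  fm <- prepare_input(model, x)
  fwd <- unet_forward_internal(model, fm, keep = FALSE, gate_mode = gates)
  from_featuremap(fwd$probs, fm$H, fm$W)
}

#' @export
predict.sa_unet <- function(object, newdata, ...) {
  unet_forward(object, newdata, ...)
}

#' @export
print.sa_unet <- function(x, ...) {
  cat(sprintf("<sa_unet> in=%d ch, widths [%s], out=%d ch, %s gates, %s parameters\n",
              x$cfg$in_channels, paste(x$cfg$widths, collapse = ","),
              x$cfg$out_channels, x$cfg$attention_gates,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Per-block shape and channel summary
#'
#' Traces an input of the given size through the layer plan and reports
#' each block's output resolution and channels, for comparison against the
#' published downsampling/upsampling tables.
#'
#' @param object An `sa_unet`.
#' @param input_size Input side length (divisible by 64); default 512.
#' @param ... Unused.
#' @return A tibble with columns `block`, `operation`, `out_size`,
#'   `out_channels`, `n_params`.
#' @export
summary.sa_unet <- function(object, input_size = 512L, ...) {
  cfg <- object$cfg
  check_input_dims(cfg, input_size, input_size)
  w <- cfg$widths
  s <- input_size
  np <- function(prefix) {
    idx <- grepl(paste0("^", prefix, "_"), names(object$params))
    sum(vapply(object$params[idx], length, integer(1)))
  }
  rows <- tibble::tribble(
    ~block, ~operation, ~out_size, ~out_channels, ~n_params,
    "FP1",  "conv block 3x3 (x3) + ReLU",            s,        w[["fp1"]],  np("enc1"),
    "FSA1", "spatial attention gate (pool /2)",      s / 2,    w[["fsa1"]], np("att1"),
    "FP2",  "conv block 3x3 (x3) + maxpool /4",      s / 8,    w[["fp2"]],  np("enc2"),
    "FP3",  "conv block 3x3 (x3) + ReLU",            s / 8,    w[["fp3"]],  np("enc3"),
    "FSA2", "spatial attention gate (pool /2)",      s / 16,   w[["fsa2"]], np("att2"),
    "FP4",  "conv block 3x3 (x3) + maxpool /4",      s / 64,   w[["fp4"]],  np("enc4"),
    "FP5",  "bottleneck conv block 3x3 (x3)",        s / 64,   w[["fp5"]],  np("bott"),
    "Dec1", "upsample x4 + concat FSA2 + conv block", s / 16,  w[["fp4"]],  np("dec1"),
    "Dec2", "upsample x2 + concat FP3 + conv block",  s / 8,   w[["fp3"]],  np("dec2"),
    "Dec3", "upsample x4 + concat FSA1 + conv block", s / 2,   w[["fsa1"]], np("dec3"),
    "Dec4", "upsample x2 + concat FP1 + conv block",  s,       w[["fp1"]],  np("dec4"),
    "Head", "conv 3x3 + sigmoid",                     s,       cfg$out_channels, np("head")
  )
  rows
}
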