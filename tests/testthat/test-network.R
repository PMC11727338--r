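# Architecture contracts: shapes, channel plan, attention behaviour, and
# the closed-form parameter count derived from the layer plan.

test_that("conv blocks map channels per the layer plan and zero weights give zero output", {
  m <- sa_unet(network_cfg(), seed = 1)
  x <- matrix(rnorm(16 * 16 * 3), 16 * 16, 3)
  out <- saunet:::conv_block_fwd(m$params, "enc1", x, 16, 16)$out
  expect_identical(ncol(out), 16L)  # 3 -> 16
  p0 <- m$params
  for (nm in grep("^enc1_", names(p0), value = TRUE)) p0[[nm]][] <- 0
  out0 <- saunet:::conv_block_fwd(p0, "enc1", x, 16, 16)$out
  expect_true(all(out0 == 0))  # ReLU(0) = 0 through all three convs
})

test_that("attention block halves resolution, doubles channels, gates in (0,1)", {
  m <- sa_unet(network_cfg(), seed = 2)
  x <- matrix(rnorm(32 * 32 * 16), 32 * 32, 16)
  a <- saunet:::attn_block_fwd(m$params, "att1", x, 32, 32, 2L)
  expect_identical(dim(a$out), c(16L * 16L, 32L))  # (32,32,16) -> (16,16,32)
  expect_true(all(a$gate > 0 & a$gate < 1))
})

test_that("zeroed gate conv gives gate == 0.5 and output == half the value path", {
  m <- sa_unet(network_cfg(), seed = 3)
  p <- m$params
  p$att1_gate_W[] <- 0; p$att1_gate_b[] <- 0
  x <- matrix(rnorm(8 * 8 * 16), 64, 16)
  a <- saunet:::attn_block_fwd(p, "att1", x, 8, 8, 2L)
  expect_true(all(a$gate == 0.5))
  mp <- saunet:::cpp_maxpool_fwd(x, 8, 8, 2L)
  v <- saunet:::conv1x1_fwd(mp$out, p$att1_val_W, p$att1_val_b)
  expect_equal(a$out, 0.5 * v)
})

test_that("attention gate pre-activation matches a brute-force pool + 1x1 mix on a tiny input", {
  set.seed(9)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  Wg <- matrix(rnorm(16), 4, 4); bg <- rnorm(4)
  Wv <- matrix(rnorm(8), 2, 4); bv <- rnorm(4)
  p <- list(t_gate_W = Wg, t_gate_b = bg, t_val_W = Wv, t_val_b = bv)
  a <- saunet:::attn_block_fwd(p, "t", matrix(x, 16, 2), 4, 4, 2L)
  # oracle: window pooling per channel, concat [avg, max], then 1x1 mix
  ap <- sapply(1:2, function(ch) as.vector(oracle_pool(x[, , ch], 2, mean)))
  mp <- sapply(1:2, function(ch) as.vector(oracle_pool(x[, , ch], 2, max)))
  z <- sweep(cbind(ap, mp) %*% Wg, 2, bg, "+")
  v <- sweep(mp %*% Wv, 2, bv, "+")
  expect_equal(a$out, (1 / (1 + exp(-z))) * v, tolerance = 1e-12)
})

test_that("encoder resolutions and channels follow the downsampling plan", {
  m <- sa_unet(network_cfg(), seed = 1)
  enc <- encoder_forward(m, array(runif(512 * 512 * 3), c(512, 512, 3)))
  expect_identical(dim(enc$bottleneck_in), c(8L, 8L, 128L))   # 512/64, 128 ch
  expect_identical(length(enc$skips), 4L)
  expect_identical(dim(enc$skips$FP1), c(512L, 512L, 16L))
  expect_identical(dim(enc$skips$FSA1), c(256L, 256L, 32L))
  expect_identical(dim(enc$skips$FP3), c(64L, 64L, 64L))
  expect_identical(dim(enc$skips$FSA2), c(32L, 32L, 128L))
  # 64 input: bottleneck collapses to 1x1
  enc64 <- encoder_forward(m, matrix(runif(64 * 64), 64, 64))
  expect_identical(dim(enc64$bottleneck_in), c(1L, 1L, 128L))
})

test_that("non-divisible input sizes are rejected with the divisibility stated", {
  m <- sa_unet(network_cfg(), seed = 1)
  expect_error(unet_forward(m, matrix(0.5, 60, 60)), "divisible by 64")
})

test_that("forward output preserves spatial dims and lies strictly in (0,1)", {
  m <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 4)
  for (s in c(64L, 128L)) {
    probs <- unet_forward(m, matrix(runif(s * s), s, s))
    expect_identical(dim(probs), c(s, s))
    expect_true(all(probs > 0 & probs < 1))
  }
})

test_that("forward is deterministic under fixed weights", {
  m <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 5)
  x <- matrix(runif(64 * 64), 64, 64)
  expect_identical(unet_forward(m, x), unet_forward(m, x))
})

test_that("summary reproduces the published channel plan at 512", {
  m <- sa_unet(network_cfg(), seed = 1)
  tab <- summary(m, input_size = 512)
  expect_equal(tab$out_channels[1:7], c(16, 32, 32, 64, 128, 128, 256))
  expect_equal(tab$out_channels[8:12], c(128, 64, 32, 16, 1))
  expect_equal(tab$out_size,
               c(512, 256, 64, 64, 32, 8, 8, 32, 64, 256, 512, 512))
  expect_identical(sum(tab$n_params), n_parameters(m))
})

test_that("trainable parameter count equals the closed-form sum over the layer plan", {
  # closed forms: a triple-conv block c_in -> c (3x3 kernels, biases) has
  #   9*c_in*c + c  +  2*(9*c*c + c)
  # an attention block on C channels has gate (2C x 2C 1x1 conv + 2C bias)
  #   and value (C x 2C 1x1 conv + 2C bias)
  conv_block_n <- function(cin, c) (9 * cin * c + c) + 2 * (9 * c * c + c)
  attn_n <- function(C) (2 * C * 2 * C + 2 * C) + (C * 2 * C + 2 * C)
  expected <- conv_block_n(3, 16) + attn_n(16) + conv_block_n(32, 32) +
    conv_block_n(32, 64) + attn_n(64) + conv_block_n(128, 128) +
    conv_block_n(128, 256) +
    conv_block_n(256 + 128, 128) + conv_block_n(128 + 64, 64) +
    conv_block_n(64 + 32, 32) + conv_block_n(32 + 16, 16) +
    (9 * 16 * 1 + 1)
  m <- sa_unet(network_cfg(), seed = 1)
  expect_identical(n_parameters(m), as.integer(expected))
  # bottleneck block alone: 3x3x128x256 + 256 plus two (3x3x256x256 + 256)
  bott <- sum(vapply(m$params[grep("^bott_", names(m$params))], length, integer(1)))
  expect_identical(bott, as.integer(conv_block_n(128, 256)))
})

test_that("forcing the attention gates open changes outputs on generic weights", {
  m <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 6)
  x <- matrix(runif(64 * 64), 64, 64)
  gated <- unet_forward(m, x, gates = "learned")
  open <- unet_forward(m, x, gates = "open")
  expect_gt(max(abs(gated - open)), 1e-6)
})

test_that("weight initialisation is seeded and reproducible", {
  m1 <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 7)
  m2 <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- sa_unet(network_cfg(width_multiplier = 1 / 8), seed = 8)
  expect_false(identical(m1$params, m3$params))
})
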