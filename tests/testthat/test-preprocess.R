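# Preprocessing: normalization conventions, paired resize/augment geometry,
# histogram equalization, and pipeline determinism.

test_that("minmax normalization spans [0,1] and handles hand cases", {
  img <- matrix(c(10, 35, 60, 20), 2, 2)
  out <- normalize_intensity(img, "minmax")
  expect_equal(out[2, 1], 0.5)          # (35-10)/(60-10)
  expect_equal(range(out), c(0, 1))
  expect_true(all(normalize_intensity(matrix(7, 3, 3), "minmax") == 0))
})

test_that("zscore normalization gives mean 0 and SD 1", {
  set.seed(1)
  img <- matrix(rnorm(64, 5, 3), 8, 8)
  out <- normalize_intensity(img, "zscore")
  expect_equal(mean(out), 0, tolerance = 1e-9)
  expect_equal(sd(out), 1, tolerance = 1e-9)
  expect_true(all(normalize_intensity(matrix(1, 4, 4), "zscore") == 0))
})

test_that("resize_pair is identity at target size and keeps masks binary", {
  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  mask <- random_mask(8)
  same <- resize_pair(img, mask, 8)
  expect_identical(same$image, img)
  expect_identical(same$mask, mask)
  up <- resize_pair(img, mask, 16)
  expect_identical(dim(up$image), c(16L, 16L))
  expect_true(all(up$mask %in% c(0L, 1L)))
  expect_error(resize_pair(img, random_mask(6), 8), "identical shapes")
})

test_that("nearest-neighbour resize preserves the foreground fraction of a checkerboard", {
  mask <- matrix(as.integer((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2 == 0), 4, 4)
  up <- resize_pair(matrix(0.5, 4, 4), mask, 8)
  expect_lt(abs(mean(up$mask) - mean(mask)), 0.05)
})

test_that("global equalization follows the empirical-CDF mapping", {
  # two-level image: 25% at the low level, 75% at the high level
  img <- matrix(c(rep(0.2, 4), rep(0.7, 12)), 4, 4)
  out <- equalize_histogram(img, "global")
  expect_equal(unique(as.vector(out))[order(unique(as.vector(img)))],
               c(0.25, 1.0))
  # ramp image (already uniform histogram): rank order preserved
  ramp <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_identical(order(as.vector(equalize_histogram(ramp, "global"))),
                   order(as.vector(ramp)))
  # constant image stays constant
  expect_equal(as.vector(equalize_histogram(matrix(0.4, 3, 3), "global")),
               rep(1, 9))
  # Kolmogorov distance to the uniform does not increase
  set.seed(3)
  skewed <- matrix(rbeta(256, 5, 1.3), 16, 16)
  kdist <- function(v) max(abs(sort(v) - seq_along(v) / length(v)))
  expect_lte(kdist(as.vector(equalize_histogram(skewed, "global"))),
             kdist(as.vector(skewed)))
})

test_that("flips are exact involutions on image and mask", {
  set.seed(4)
  img <- matrix(runif(64), 8, 8)
  mask <- random_mask(8)
  cfg <- preprocess_cfg(target_size = 8, augment = "flip")
  tr <- list(angle = 0, dr = 0L, dc = 0L, flip_h = TRUE, flip_v = FALSE)
  once <- saunet:::apply_transform(img, mask, tr)
  twice <- saunet:::apply_transform(once$image, once$mask, tr)
  expect_identical(twice$image, img)
  expect_identical(twice$mask, mask)
})

test_that("identity transform and exact single-pixel translation", {
  img <- matrix(0, 8, 8); mask <- matrix(0L, 8, 8)
  mask[4, 5] <- 1L; img[4, 5] <- 1
  idt <- saunet:::apply_transform(img, mask, list(angle = 0, dr = 0L, dc = 0L,
                                                  flip_h = FALSE, flip_v = FALSE))
  expect_identical(idt$image, img)
  tr <- saunet:::apply_transform(img, mask, list(angle = 0, dr = 3L, dc = 0L,
                                                 flip_h = FALSE, flip_v = FALSE))
  expect_identical(which(tr$mask == 1L), which(mask == 1L) + 3L)  # moved by (3,0)
})

test_that("augment_pair applies the same seeded transform to image and mask", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- random_mask(64, 0.2)
  cfg <- preprocess_cfg(target_size = 64)
  a1 <- augment_pair(img, mask, cfg, seed = 42)
  a2 <- augment_pair(img, mask, cfg, seed = 42)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_true(all(a1$mask %in% c(0L, 1L)))
  # the binary mask transformed as an image (nearest) matches the mask path
  img_as_mask <- augment_pair(mask + 0, mask, cfg, seed = 42)
  expect_identical(img_as_mask$mask, a1$mask)
})

test_that("pipeline composition: shape, minmax range, binarity, determinism", {
  sp <- phantom_spec(image_size = 48, seed = 31)
  pair <- generate_phantom(sp)
  cfg <- preprocess_cfg(target_size = 64, normalize = "minmax", equalize = "off",
                        denoise = "off", augment = character(0))
  pipe <- build_pipeline(cfg)
  out1 <- pipe(pair); out2 <- pipe(pair)
  expect_identical(out1$image, out2$image)   # deterministic without augmentation
  expect_identical(dim(out1$image), c(64L, 64L))
  expect_equal(range(out1$image), c(0, 1))   # minmax on a non-constant input
  expect_true(all(out1$mask %in% c(0L, 1L)))
  # every stage preserves binarity, including equalize/denoise/augment modes
  full <- build_pipeline(preprocess_cfg(target_size = 64, equalize = "global",
                                        denoise = "gaussian"), train = TRUE)
  outf <- full(pair, seed = 7)
  expect_true(all(outf$mask %in% c(0L, 1L)))
  expect_identical(outf$image, full(pair, seed = 7)$image)  # seeded reruns identical
})

test_that("invalid preprocessing configurations error at build time", {
  expect_error(preprocess_cfg(target_size = 0), "positive")
  expect_error(preprocess_cfg(rotate_range = c(-200, 15)), "180")
  expect_error(preprocess_cfg(augment = "zoom"), "subset")
  expect_error(equalize_histogram(matrix(c(-1, 2, 0, 1), 2, 2), "global"), "normalized")
})
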