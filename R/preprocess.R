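# Preprocessing pipeline: normalization -> resizing -> histogram
# equalization -> denoising on images; resizing and geometric augmentation
# applied jointly to image and mask so the pair stays aligned. Masks are
# resampled nearest-neighbour and re-binarized after every geometric stage.

#' Preprocessing configuration
#'
#' @param target_size Output side length in pixels (default 512).
#' @param normalize Intensity normalization: `"minmax"` or `"zscore"`.
#' @param equalize Histogram equalization: `"global"` (exact empirical-CDF
#'   mapping), `"adaptive"` (CLAHE), or `"off"`.
#' @param denoise `"gaussian"`, `"median"`, or `"off"`.
#' @param denoise_strength Gaussian sigma in px (or median half-window);
#'   default 0.5.
#' @param augment Character subset of `c("rotate", "translate", "flip")`;
#'   applied only when a pipeline is built with `train = TRUE`.
#' @param rotate_range Rotation range in degrees, within `[-180, 180]`.
#' @param translate_frac Max translation as a fraction of `target_size`.
#' @param seed Integer seed for augmentation draws.
#' @return A validated `preprocess_cfg` list.
#' @export
preprocess_cfg <- function(target_size = 512L,
                           normalize = c("minmax", "zscore"),
                           equalize = c("global", "adaptive", "off"),
                           denoise = c("gaussian", "median", "off"),
                           denoise_strength = 0.5,
                           augment = c("rotate", "translate", "flip"),
                           rotate_range = c(-15, 15),
                           translate_frac = 0.05,
                           seed = 1L) {
  normalize <- match.arg(normalize)
  equalize <- match.arg(equalize)
  denoise <- match.arg(denoise)
  if (target_size <= 0) stop("target_size must be positive", call. = FALSE)
  if (!all(augment %in% c("rotate", "translate", "flip"))) {
    stop("augment must be a subset of {rotate, translate, flip}", call. = FALSE)
  }
  if (any(abs(rotate_range) > 180)) stop("rotate_range must lie in [-180, 180]", call. = FALSE)
  if (translate_frac < 0 || translate_frac >= 1) {
    stop("translate_frac must be in [0, 1) of target_size", call. = FALSE)
  }
  structure(list(target_size = as.integer(target_size), normalize = normalize,
                 equalize = equalize, denoise = denoise,
                 denoise_strength = denoise_strength, augment = augment,
                 rotate_range = rotate_range, translate_frac = translate_frac,
                 seed = as.integer(seed)),
            class = "preprocess_cfg")
}

#' Normalize image intensities
#'
#' `"minmax"` maps the range onto exactly `[0, 1]`; `"zscore"` standardizes
#' to mean 0, SD 1. A constant image maps to all zeros under either mode
#' (rather than dividing by zero).
#'
#' @param img Numeric matrix.
#' @param mode `"minmax"` or `"zscore"`.
#' @return Matrix of the same shape.
#' @export
normalize_intensity <- function(img, mode = c("minmax", "zscore")) {
  mode <- match.arg(mode)
  if (length(img) == 0) stop("image is empty", call. = FALSE)
  rng <- range(img)
  if (rng[1] == rng[2]) return(img * 0)
  if (mode == "minmax") {
    (img - rng[1]) / (rng[2] - rng[1])
  } else {
    (img - mean(img)) / sd(img)
  }
}

as_ebimage_matrix <- function(x) {
  # EBImage operates on plain matrices; keep dims, strip Image class on return
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Resize an image/mask pair to a square target size
#'
#' Image is interpolated bilinearly; the mask is resampled
#' nearest-neighbour and therefore stays strictly binary. An identity
#' resize returns the inputs bit-identically.
#'
#' @param img Numeric matrix.
#' @param mask Binary matrix, same shape as `img`.
#' @param target_size Output side length.
#' @return List with `image` and `mask`, both `target_size x target_size`.
#' @export
resize_pair <- function(img, mask, target_size) {
  assert_same_shape(img, mask, "image and mask")
  assert_binary_mask(mask)
  if (all(dim(img) == c(target_size, target_size))) {
    return(list(image = img, mask = mask))
  }
  im <- as_ebimage_matrix(EBImage::resize(img, target_size, target_size))
  mk <- as_ebimage_matrix(EBImage::resize(mask + 0, target_size, target_size,
                                          filter = "none"))
  list(image = im, mask = matrix(as.integer(mk >= 0.5), target_size, target_size))
}

#' Histogram equalization
#'
#' `"global"` applies the exact empirical-CDF mapping (each intensity v maps
#' to the fraction of pixels <= v), which flattens the intensity histogram
#' and is rank-preserving. `"adaptive"` applies contrast-limited adaptive
#' equalization (CLAHE) on local tiles.
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param mode `"global"`, `"adaptive"`, or `"off"`.
#' @return Matrix with values in `[0, 1]`.
#' @export
equalize_histogram <- function(img, mode = c("global", "adaptive", "off")) {
  mode <- match.arg(mode)
  if (mode == "off") return(img)
  if (min(img) < 0 || max(img) > 1) {
    stop("equalize_histogram expects intensities normalized to [0, 1]", call. = FALSE)
  }
  if (mode == "global") {
    out <- ecdf(as.vector(img))(img)
    matrix(out, nrow(img), ncol(img))
  } else {
    as_ebimage_matrix(EBImage::clahe(img, nx = 4L, bins = 256L, limit = 2))
  }
}

#' Denoise an image
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param method `"gaussian"` (blur with sigma = `strength` px), `"median"`
#'   (window half-width `max(1, round(strength))`), or `"off"`.
#' @param strength Filter strength; default 0.5 px.
#' @return Matrix of the same shape.
#' @export
denoise_image <- function(img, method = c("gaussian", "median", "off"), strength = 0.5) {
  method <- match.arg(method)
  switch(method,
    off = img,
    gaussian = as_ebimage_matrix(EBImage::gblur(img, sigma = strength)),
    median = as_ebimage_matrix(EBImage::medianFilter(pmin(pmax(img, 0), 1),
                                                     size = max(1L, as.integer(round(strength))))))
}

# Exact geometric primitives applied identically to image and mask.

flip_image <- function(img, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (axis == "horizontal") img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

# integer translation by (dr, dc) with zero fill; exact index arithmetic
translate_image <- function(img, dr, dc, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - dr; src_c <- seq_len(W) - dc
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

rotate_image <- function(img, angle, nearest = FALSE) {
  if (angle == 0) return(img)
  as_ebimage_matrix(EBImage::rotate(img, angle,
                                    filter = if (nearest) "none" else "bilinear",
                                    output.dim = dim(img), bg.col = 0))
}

#' Apply a seeded random geometric augmentation to an image/mask pair
#'
#' Draws one transform (rotation angle, integer translation, flips) from the
#' configured ranges and applies it identically to image and mask. The mask
#' is resampled nearest-neighbour and re-binarized; out-of-bounds pixels are
#' filled with background 0. The draw is fully determined by `seed`.
#'
#' @param img Numeric matrix.
#' @param mask Binary matrix, same shape.
#' @param cfg A [preprocess_cfg()].
#' @param seed Integer seed for the transform draw.
#' @return List with `image`, `mask`, and `transform` (the drawn parameters).
#' @export
augment_pair <- function(img, mask, cfg = preprocess_cfg(), seed = cfg$seed) {
  assert_same_shape(img, mask, "image and mask")
  assert_binary_mask(mask)
  tr <- with_seed(seed, list(
    angle = if ("rotate" %in% cfg$augment) runif(1, cfg$rotate_range[1], cfg$rotate_range[2]) else 0,
    dr = if ("translate" %in% cfg$augment)
      sample.int(2 * floor(cfg$translate_frac * nrow(img)) + 1L, 1L) -
        floor(cfg$translate_frac * nrow(img)) - 1L else 0L,
    dc = if ("translate" %in% cfg$augment)
      sample.int(2 * floor(cfg$translate_frac * ncol(img)) + 1L, 1L) -
        floor(cfg$translate_frac * ncol(img)) - 1L else 0L,
    flip_h = "flip" %in% cfg$augment && runif(1) < 0.5,
    flip_v = "flip" %in% cfg$augment && runif(1) < 0.5
  ))
  out <- apply_transform(img, mask, tr)
  c(out, list(transform = tr))
}

apply_transform <- function(img, mask, tr) {
  if (tr$angle != 0) {
    img <- rotate_image(img, tr$angle, nearest = FALSE)
    mask <- rotate_image(mask + 0, tr$angle, nearest = TRUE)
  }
  if (tr$dr != 0 || tr$dc != 0) {
    img <- translate_image(img, tr$dr, tr$dc)
    mask <- translate_image(mask + 0, tr$dr, tr$dc)
  }
  if (isTRUE(tr$flip_h)) { img <- flip_image(img, "horizontal"); mask <- flip_image(mask, "horizontal") }
  if (isTRUE(tr$flip_v)) { img <- flip_image(img, "vertical"); mask <- flip_image(mask, "vertical") }
  list(image = img, mask = matrix(as.integer(mask >= 0.5), nrow(img), ncol(img)))
}

#' Build a preprocessing pipeline closure
#'
#' Returns a function that maps a `phantom_pair` (or any list with `image`
#' and `mask`) through normalize -> resize -> equalize -> denoise, plus a
#' seeded random augmentation when `train = TRUE`. Without augmentation the
#' pipeline is fully deterministic; with it, determinism follows from
#' `cfg$seed` and the per-pair `seed` argument.
#'
#' @param cfg A [preprocess_cfg()].
#' @param train If `TRUE`, apply augmentation.
#' @return A function `(pair, seed)` returning a transformed pair.
#' @export
build_pipeline <- function(cfg = preprocess_cfg(), train = FALSE) {
  stopifnot(inherits(cfg, "preprocess_cfg"))
  function(pair, seed = cfg$seed) {
    img <- normalize_intensity(pair$image, cfg$normalize)
    rs <- resize_pair(img, pair$mask, cfg$target_size)
    img <- rs$image; mask <- rs$mask
    if (cfg$equalize != "off") {
      # z-scored intensities are re-ranged for the CDF mapping
      if (cfg$normalize == "zscore") img <- normalize_intensity(img, "minmax")
      img <- equalize_histogram(img, cfg$equalize)
    }
    if (cfg$denoise != "off") img <- denoise_image(img, cfg$denoise, cfg$denoise_strength)
    # resizing/equalization/denoising all shrink the dynamic range slightly;
    # in minmax mode the pipeline guarantees the output spans [0, 1]
    if (cfg$normalize == "minmax" && diff(range(img)) > 0) {
      img <- normalize_intensity(img, "minmax")
    }
    if (train && length(cfg$augment) > 0) {
      aug <- augment_pair(img, mask, cfg, seed = seed)
      img <- aug$image; mask <- aug$mask
    }
    out <- pair
    out$image <- img
    out$mask <- mask
    out
  }
}
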