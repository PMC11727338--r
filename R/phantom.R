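#' Specify an MRI-like segmentation phantom
#'
#' A phantom is a smooth low-frequency background field with a number of
#' irregular elliptical lesions at a fixed intensity offset (`contrast`)
#' above the background, plus additive noise, and a pixel-exact binary
#' ground-truth mask. Scenarios mirror the failure regimes that make tumor
#' segmentation hard in practice: low-contrast boundaries, small lesions,
#' and overlapping lesions that merge into one connected region.
#'
#' Scenario presets (applied only to arguments left at their defaults):
#' * `default`: moderate contrast (0.45), radii between 1/12 and 1/5 of the
#'   image side.
#' * `low_contrast`: contrast 0.15 — strictly smaller foreground/background
#'   gap than `default`.
#' * `small_tumor`: radii 2-4 px, lesions easy to overlook.
#' * `overlapping`: at least 2 lesions placed close enough that a pair
#'   touches or overlaps.
#'
#' @param image_size Pixels per side (square image).
#' @param n_lesions Number of lesions (>= 0).
#' @param lesion_radius_range Length-2 numeric, min/max lesion radius in px.
#' @param contrast Foreground/background intensity gap in `[0, 1]`.
#' @param noise_sd SD of additive noise, intensity units.
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param scenario One of `"default"`, `"low_contrast"`, `"small_tumor"`,
#'   `"overlapping"`.
#' @param seed Integer seed; the same spec and seed give bit-identical output.
#' @return A `phantom_spec` object (a validated list).
#' @export
phantom_spec <- function(image_size = 128L,
                         n_lesions = 2L,
                         lesion_radius_range = NULL,
                         contrast = NULL,
                         noise_sd = 0.03,
                         noise_model = c("gaussian", "rician"),
                         scenario = c("default", "low_contrast", "small_tumor", "overlapping"),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  noise_model <- match.arg(noise_model)
  if (is.null(contrast)) {
    contrast <- switch(scenario, low_contrast = 0.15, 0.45)
  }
  if (is.null(lesion_radius_range)) {
    lesion_radius_range <- switch(scenario,
      small_tumor = c(2, 4),
      round(c(image_size / 12, image_size / 5)))
  }
  if (scenario == "overlapping") n_lesions <- max(n_lesions, 2L)

  spec <- structure(list(
    image_size = as.integer(image_size),
    n_lesions = as.integer(n_lesions),
    lesion_radius_range = as.numeric(lesion_radius_range),
    contrast = contrast,
    noise_sd = noise_sd,
    noise_model = noise_model,
    scenario = scenario,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  rr <- spec$lesion_radius_range
  if (spec$image_size < 8) stop("image_size must be at least 8 px", call. = FALSE)
  if (spec$n_lesions < 0) stop("n_lesions must be >= 0", call. = FALSE)
  if (length(rr) != 2 || rr[1] > rr[2]) {
    stop("lesion_radius_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (spec$n_lesions > 0 && (rr[1] < 1 || rr[2] > spec$image_size / 2)) {
    stop("lesion radii must lie in [1, image_size/2]; lesion placement impossible",
         call. = FALSE)
  }
  if (spec$contrast < 0 || spec$contrast > 1) stop("contrast must be in [0, 1]", call. = FALSE)
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  invisible(spec)
}

# Smooth low-frequency background: a coarse seeded grid, bilinearly
# interpolated to full resolution. `level` shifts the overall brightness
# (used for per-patient style).
phantom_background <- function(n, level = 0.3, amplitude = 0.1) {
  g <- 5L
  coarse <- matrix(runif(g * g, level - amplitude, level + amplitude), g, g)
  # bilinear interpolation of the coarse grid onto the n x n grid
  s <- seq(1, g, length.out = n)
  i0 <- pmin(floor(s), g - 1L); fr <- s - i0
  rows <- coarse[i0, , drop = FALSE] * (1 - fr) + coarse[i0 + 1L, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] * rep(1 - fr, each = n) +
    rows[, i0 + 1L, drop = FALSE] * rep(fr, each = n)
}

# Rasterize one irregular lesion: an ellipse whose radius is modulated by a
# low-order Fourier perturbation of the polar angle, keeping the effective
# radius within [0.75 r, 1.25 r].
lesion_mask <- function(n, center, radius, eccentricity = NULL) {
  ecc <- eccentricity %||% runif(1, 0.7, 1.3)
  theta0 <- runif(1, 0, 2 * pi)
  a <- runif(2, -1, 1)
  ph <- runif(2, 0, 2 * pi)
  rr <- matrix(seq_len(n), n, n) - center[1]
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - center[2]
  u <- rr * cos(theta0) + cc * sin(theta0)
  v <- (-rr * sin(theta0) + cc * cos(theta0)) / ecc
  d <- sqrt(u^2 + v^2)
  ang <- atan2(v, u)
  bump <- 0.1 * (a[1] * sin(2 * ang + ph[1]) + a[2] * sin(3 * ang + ph[2]))
  # normalise so the enclosed area is ~ pi * radius^2 whatever the
  # eccentricity; the clamp bounds the equivalent radius to [0.78r, 1.22r]
  rho <- radius / sqrt(ecc) * pmin(pmax(1 + bump, 0.78), 1.22)
  (d <= rho) * 1L
}

#' Generate a single phantom image/mask pair
#'
#' Deterministic for a fixed spec: the same spec (including its `seed`)
#' yields bit-identical image and mask across calls and processes.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Identifier stored with the pair.
#' @param style Optional per-patient style list with elements
#'   `background_level` and `radius_scale` (used by [generate_dataset()] so
#'   slices from one patient look alike).
#' @return A `phantom_pair`: list with `image` (H x W matrix in `[0, 1]`),
#'   `mask` (H x W integer matrix in `{0, 1}`), `patient_id`, and `spec`.
#' @export
generate_phantom <- function(spec, patient_id = "P001", style = NULL) {
  validate_phantom_spec(spec)
  n <- spec$image_size
  with_seed(spec$seed, {
    bg_level <- style$background_level %||% 0.3
    rscale <- style$radius_scale %||% 1
    img <- phantom_background(n, level = bg_level)
    mask <- matrix(0L, n, n)
    rr <- pmax(1, pmin(spec$lesion_radius_range * rscale, n / 2))
    centers <- list()
    if (spec$n_lesions > 0) {
      radii <- runif(spec$n_lesions, rr[1], rr[2])
      for (i in seq_len(spec$n_lesions)) {
        r <- radii[i]
        margin <- ceiling(1.25 * r * 1.3) + 1  # irregularity + eccentricity head-room
        if (2 * margin >= n) {
          stop("lesion radius too large for image_size: placement impossible", call. = FALSE)
        }
        if (spec$scenario == "overlapping" && i > 1) {
          # place near a previous lesion so the pair touches or overlaps
          base <- centers[[sample.int(i - 1L, 1L)]]
          dist <- 0.7 * (base$r + r)
          ang <- runif(1, 0, 2 * pi)
          ctr <- pmin(pmax(base$ctr + dist * c(cos(ang), sin(ang)), margin), n - margin)
        } else {
          ctr <- runif(2, margin, n - margin)
        }
        centers[[i]] <- list(ctr = ctr, r = r)
        mask <- pmax(mask, lesion_mask(n, ctr, r))
      }
    }
    img <- img + spec$contrast * mask
    if (spec$noise_sd > 0) {
      img <- switch(spec$noise_model,
        gaussian = img + rnorm(n * n, 0, spec$noise_sd),
        rician = sqrt((img + rnorm(n * n, 0, spec$noise_sd))^2 +
                        rnorm(n * n, 0, spec$noise_sd)^2))
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = matrix(as.integer(mask), n, n),
                   patient_id = patient_id, spec = spec),
              class = "phantom_pair")
  })
}

#' Generate a multi-patient phantom dataset with a manifest
#'
#' Each patient gets correlated style parameters (background brightness,
#' lesion size scale) shared across their slices, so that patient-wise
#' splits are meaningfully different from slice-wise splits and leakage is
#' detectable. Slice-level content (lesion placement, noise) varies.
#'
#' @param spec A [phantom_spec()]; its `seed` drives everything.
#' @param n_patients Number of patients (>= 2).
#' @param slices_per_patient Slices generated per patient.
#' @return A list with `pairs` (list of `phantom_pair`) and `manifest`
#'   (a tibble with `patient_id`, `slice`, `pair_id`).
#' @export
generate_dataset <- function(spec, n_patients, slices_per_patient = 1L) {
  validate_phantom_spec(spec)
  if (n_patients < 2) stop("n_patients must be >= 2 (patient split untestable otherwise)",
                           call. = FALSE)
  styles <- with_seed(spec$seed, {
    lapply(seq_len(n_patients), function(i) {
      list(background_level = runif(1, 0.2, 0.42),
           radius_scale = runif(1, 0.85, 1.15))
    })
  })
  pairs <- list()
  rows <- list()
  k <- 0L
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    for (s in seq_len(slices_per_patient)) {
      k <- k + 1L
      slice_spec <- spec
      slice_spec$seed <- derive_seed(spec$seed, k)
      pairs[[k]] <- generate_phantom(slice_spec, patient_id = pid, style = styles[[p]])
      rows[[k]] <- tibble::tibble(patient_id = pid, slice = s, pair_id = k)
    }
  }
  list(pairs = pairs, manifest = dplyr::bind_rows(rows))
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("<phantom_pair> %s: %dx%d image, %d foreground px (%s scenario)\n",
              x$patient_id, nrow(x$image), ncol(x$image), sum(x$mask),
              x$spec$scenario))
  invisible(x)
}

#' Plot a phantom pair (image with mask outline)
#'
#' @param object A `phantom_pair`.
#' @param ... Unused.
#' @return A ggplot object showing the image raster and the mask contour.
#' @export
autoplot.phantom_pair <- function(object, ...) {
  df <- tidyr::expand_grid(col = seq_len(ncol(object$image)),
                           row = seq_len(nrow(object$image)))
  df$intensity <- as.vector(object$image)
  df$mask <- as.vector(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$patient_id, x = NULL, y = NULL)
}
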