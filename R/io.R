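# File I/O (PNG / TIFF / NIfTI images, CSV manifests, YAML/JSON config),
# dataset writing, and the multi-seed experiment runner.
#
# Images are read as float matrices in [0, 1], origin top-left, (row, col)
# indexing. Masks are binarized at half their dynamic range.

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) {
    stop(sprintf("unsupported image format '.%s' (use PNG, TIFF or NIfTI)", ext),
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path))
  if (length(dim(x)) == 3) {
    # collapse color/alpha planes to grayscale luminance
    x <- apply(x[, , seq_len(min(3, dim(x)[3])), drop = FALSE], c(1, 2), mean)
  }
  x
}

#' Read an image file as a float matrix on the unit interval
#'
#' Supports PNG, TIFF and NIfTI (a 3-D NIfTI volume requires `slice`, taken
#' along the last axis). Color images are collapsed to grayscale. Use
#' [replicate_channels()] for networks expecting 3 input channels.
#'
#' @param path File path.
#' @param slice Slice index for 3-D NIfTI volumes.
#' @return `H x W` numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path, slice = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nii", "gz")) {
    vol <- RNifti::readNifti(path)
    d <- dim(vol)
    if (length(d) == 2) {
      x <- vol[, ]
    } else if (length(d) == 3) {
      if (is.null(slice)) {
        stop("3-D NIfTI volume: a slice index along the last axis is required",
             call. = FALSE)
      }
      x <- vol[, , slice]
    } else {
      stop("only 2-D or 3-D NIfTI images are supported", call. = FALSE)
    }
    rng <- range(x)
    if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
    return(matrix(as.double(x), nrow(x), ncol(x)))
  }
  read_raster(path)
}

#' Read a mask file as a binary matrix
#'
#' The raster is binarized at half its dynamic range (pixels above
#' `min + (max-min)/2` are foreground), so 8-bit 0/255 and float 0/1 masks
#' both round-trip exactly.
#'
#' @inheritParams read_image
#' @return `H x W` integer matrix with values in `{0, 1}`.
#' @export
read_mask <- function(path, slice = NULL) {
  x <- read_image(path, slice = slice)
  rng <- range(x)
  thr <- if (rng[2] > rng[1]) rng[1] + (rng[2] - rng[1]) / 2 else 0.5
  matrix(as.integer(x >= thr), nrow(x), ncol(x))
}

#' Replicate a grayscale matrix across channels
#'
#' @param img `H x W` matrix.
#' @param n_channels Number of identical channels wanted.
#' @return `H x W x n_channels` array (or the matrix itself if `n == 1`).
#' @export
replicate_channels <- function(img, n_channels) {
  if (n_channels == 1) return(img)
  array(rep(as.double(img), n_channels), dim = c(nrow(img), ncol(img), n_channels))
}

#' Write an image (or mask) as an 8-bit PNG
#'
#' @param img Numeric matrix in `[0, 1]` (masks in `{0, 1}` map to 0/255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a phantom dataset to disk with a CSV manifest
#'
#' Writes `images/<patient>_<slice>.png` and `masks/<patient>_<slice>.png`
#' under `dir` plus `manifest.csv` with columns `patient_id`, `image_path`,
#' `mask_path`, `split`.
#'
#' @param dataset A list with `pairs` and `manifest` from
#'   [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param split Optional [patient_split()] result used to fill the `split`
#'   column (otherwise `"unassigned"`).
#' @return The manifest tibble (with file paths), invisibly.
#' @export
write_dataset <- function(dataset, dir, split = NULL) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  mf <- dataset$manifest
  img_path <- file.path(dir, "images", sprintf("%s_s%02d.png", mf$patient_id, mf$slice))
  mask_path <- file.path(dir, "masks", sprintf("%s_s%02d.png", mf$patient_id, mf$slice))
  for (i in seq_along(dataset$pairs)) {
    write_image_png(dataset$pairs[[i]]$image, img_path[i])
    write_image_png(dataset$pairs[[i]]$mask, mask_path[i])
  }
  tag <- rep("unassigned", nrow(mf))
  if (!is.null(split)) {
    tag <- ifelse(mf$patient_id %in% split$train, "train", "test")
  }
  out <- tibble::tibble(patient_id = mf$patient_id, image_path = img_path,
                        mask_path = mask_path, split = tag)
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Read and validate a dataset manifest
#'
#' Checks that referenced files exist and that no patient appears in more
#' than one split (patient leakage).
#'
#' @param path Path to a manifest CSV with columns `patient_id`,
#'   `image_path`, `mask_path`, `split`.
#' @return The manifest as a tibble.
#' @export
read_manifest <- function(path) {
  mf <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("patient_id", "image_path", "mask_path", "split")
  missing_cols <- setdiff(need, names(mf))
  if (length(missing_cols) > 0) {
    stop(sprintf("manifest is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  missing_files <- c(mf$image_path, mf$mask_path)
  missing_files <- missing_files[!file.exists(missing_files)]
  if (length(missing_files) > 0) {
    stop(sprintf("manifest references missing file(s), e.g. %s", missing_files[1]),
         call. = FALSE)
  }
  leaks <- tapply(mf$split, mf$patient_id, function(s) length(unique(s)))
  if (any(leaks > 1)) {
    stop(sprintf("patient leakage: patient(s) %s appear in more than one split",
                 paste(names(leaks)[leaks > 1], collapse = ", ")), call. = FALSE)
  }
  mf
}

# ---- configuration ----------------------------------------------------------

default_config <- function() {
  list(
    phantom = list(image_size = 64L, n_lesions = 2L, contrast = 0.45,
                   noise_sd = 0.03, scenario = "default",
                   n_patients = 10L, slices_per_patient = 2L),
    preprocess = list(target_size = 64L, normalize = "minmax", equalize = "off",
                      denoise = "off", denoise_strength = 0.5,
                      augment = character(0), rotate_range = c(-15, 15),
                      translate_frac = 0.05),
    network = list(in_channels = 3L, base_width = 16L, width_multiplier = 0.25,
                   out_channels = 1L, attention_gates = "learned", residual = FALSE),
    train = list(epochs = 10L, batch_size = 8L, optimizer = "adam", lr = 1e-3,
                 train_fraction = 0.8, stop_when_val_dsc = NULL),
    postprocess = list(threshold = 0.5, min_size = 10, connectivity = 8L,
                       mode = "filter")
  )
}

merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      stop(sprintf("unknown config key '%s%s'", path, nm), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      # index assignment so an explicit null keeps the key (as NULL)
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Load a run configuration (YAML or JSON) with validation
#'
#' Unknown keys are rejected with the offending field named; omitted keys
#' take documented defaults. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file, or `NULL`
#'   for all defaults.
#' @return A nested named list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext),
         call. = FALSE))
  if (is.null(user)) return(defaults)
  # enum validation with the field named
  cfg <- merge_config(defaults, user)
  # normalise YAML round-trip artifacts (empty sequences load as lists)
  cfg$preprocess$augment <- as.character(unlist(cfg$preprocess$augment))
  cfg$preprocess$rotate_range <- as.numeric(unlist(cfg$preprocess$rotate_range))
  enums <- list(
    c("preprocess", "normalize", "minmax", "zscore"),
    c("preprocess", "equalize", "global", "adaptive", "off"),
    c("preprocess", "denoise", "gaussian", "median", "off"),
    c("phantom", "scenario", "default", "low_contrast", "small_tumor", "overlapping"),
    c("network", "attention_gates", "learned", "open"),
    c("postprocess", "mode", "filter", "largest")
  )
  for (e in enums) {
    val <- cfg[[e[1]]][[e[2]]]
    if (!val %in% e[-(1:2)]) {
      stop(sprintf("invalid value '%s' for config field %s.%s", val, e[1], e[2]),
           call. = FALSE)
    }
  }
  cfg
}

#' Write a configuration to YAML
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# ---- multi-seed experiment --------------------------------------------------

#' Run the full train/evaluate pipeline over several seeds and aggregate
#'
#' For each seed: generate a phantom dataset, preprocess, split by patient,
#' train, evaluate on the held-out patients with postprocessing, and collect
#' the metric means. Per-metric mean, SD and t-based 95% CI over the runs
#' are then computed with [aggregate_runs()].
#'
#' @param cfg Configuration list from [load_config()] (defaults if `NULL`).
#' @param n_seeds Number of independent runs (>= 2).
#' @param seeds Optional explicit integer seeds (length `n_seeds`).
#' @return An `experiment_report`: list with `per_run` (tibble, one row per
#'   seed) and `aggregate` (tibble from [aggregate_runs()]).
#' @export
run_experiment <- function(cfg = NULL, n_seeds = 2L, seeds = NULL) {
  if (is.null(cfg)) cfg <- default_config()
  if (is.null(seeds)) seeds <- seq_len(n_seeds)
  if (length(seeds) < 2) stop("run_experiment requires >= 2 seeds", call. = FALSE)
  runs <- lapply(seeds, function(s) {
    res <- run_single(cfg, seed = s)
    dplyr::bind_cols(tibble::tibble(seed = s), glance(res$report)[
      , c("dsc", "precision", "recall", "accuracy", "auc", "hd95")])
  })
  per_run <- dplyr::bind_rows(runs)
  structure(list(per_run = per_run,
                 aggregate = aggregate_runs(per_run[, -1])),
            class = "experiment_report")
}

# One seeded end-to-end run: generate -> preprocess -> split -> train ->
# evaluate. Exposed for the CLI and the acceptance workflow.
#' @rdname run_experiment
#' @param seed Integer seed for a single run.
#' @export
run_single <- function(cfg = NULL, seed = 1L) {
  if (is.null(cfg)) cfg <- default_config()
  ph <- cfg$phantom
  spec <- phantom_spec(image_size = ph$image_size, n_lesions = ph$n_lesions,
                       contrast = ph$contrast, noise_sd = ph$noise_sd,
                       scenario = ph$scenario, seed = seed)
  ds <- generate_dataset(spec, ph$n_patients, ph$slices_per_patient)
  pp <- cfg$preprocess
  pipe <- build_pipeline(preprocess_cfg(
    target_size = pp$target_size, normalize = pp$normalize, equalize = pp$equalize,
    denoise = pp$denoise, denoise_strength = pp$denoise_strength,
    augment = pp$augment, rotate_range = pp$rotate_range,
    translate_frac = pp$translate_frac, seed = seed))
  pairs <- lapply(ds$pairs, pipe)
  split <- patient_split(ds$manifest, cfg$train$train_fraction, seed = seed)
  nw <- cfg$network
  model <- sa_unet(network_cfg(in_channels = nw$in_channels, base_width = nw$base_width,
                               width_multiplier = nw$width_multiplier,
                               out_channels = nw$out_channels,
                               attention_gates = nw$attention_gates,
                               residual = nw$residual), seed = seed)
  tc <- cfg$train
  fit <- train_unet(model, pairs, split,
                    train_cfg(epochs = tc$epochs, batch_size = tc$batch_size,
                              lr = tc$lr, train_fraction = tc$train_fraction,
                              seed = seed, stop_when_val_dsc = tc$stop_when_val_dsc))
  test_pairs <- pairs[vapply(pairs, function(p) p$patient_id, character(1)) %in% split$test]
  report <- evaluate_run(fit, test_pairs, threshold = cfg$postprocess$threshold,
                         min_size = cfg$postprocess$min_size)
  list(fit = fit, report = report, split = split)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d run(s)\n", nrow(x$per_run)))
  print(x$aggregate)
  invisible(x)
}

#' Tidy an experiment report
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-run metric tibble.
#' @export
tidy.experiment_report <- function(x, ...) x$per_run

#' Aggregate summary of an experiment report
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The per-metric mean/SD/CI tibble.
#' @export
glance.experiment_report <- function(x, ...) x$aggregate
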