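# Training: binary cross-entropy loss, patient-wise splitting, Adam, and
# the seeded training/validation loop.

#' Binary cross-entropy loss over pixels
#'
#' `-(1/N) sum( y*log(y') + (1-y)*log(1-y') )` with predicted probabilities
#' clipped to `[eps, 1-eps]` (default `eps = 1e-7`) before taking logs.
#'
#' @param y Ground-truth labels in `{0, 1}` (any shape).
#' @param probs Predicted probabilities, congruent shape.
#' @param eps Clipping constant.
#' @return Nonnegative scalar; 0 iff predictions equal truth exactly
#'   (before clipping).
#' @export
bce_loss <- function(y, probs, eps = 1e-7) {
  assert_same_shape(y, probs, "y and probs")
  p <- pmin(pmax(as.vector(probs), eps), 1 - eps)
  yv <- as.vector(y)
  -mean(yv * log(p) + (1 - yv) * log(1 - p))
}

#' Split a manifest by patient identity
#'
#' All slices of a patient land in exactly one side. The number of training
#' patients is `round(train_fraction * n_patients)`, clamped so both sides
#' are nonempty.
#'
#' @param manifest Data frame with a `patient_id` column.
#' @param train_fraction Fraction of patients assigned to training
#'   (default 0.8).
#' @param seed Integer seed for the patient shuffle.
#' @return List with `train` and `test` character vectors of patient ids
#'   (disjoint, covering all patients).
#' @export
patient_split <- function(manifest, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  ids <- unique(as.character(manifest$patient_id))
  if (length(ids) < 2) stop("patient split requires >= 2 patients", call. = FALSE)
  n_train <- min(max(round(train_fraction * length(ids)), 1L), length(ids) - 1L)
  shuffled <- with_seed(seed, sample(ids))
  list(train = sort(shuffled[seq_len(n_train)]),
       test = sort(shuffled[-seq_len(n_train)]))
}

#' Training configuration
#'
#' @param epochs Maximum epochs (default 200).
#' @param batch_size Images per gradient step (default 8).
#' @param optimizer Only `"adam"` is implemented.
#' @param lr Learning rate (default 1e-4).
#' @param train_fraction Patient fraction for training (default 0.8).
#' @param seed Seed for shuffling and any stochastic choice in the loop.
#' @param stop_when_val_dsc Optional early-stop target: training ends once
#'   the validation mean DSC reaches this value.
#' @param verbose Print per-epoch progress.
#' @return A `train_cfg` list.
#' @export
train_cfg <- function(epochs = 200L, batch_size = 8L, optimizer = "adam",
                      lr = 1e-4, train_fraction = 0.8, seed = 1L,
                      stop_when_val_dsc = NULL, verbose = FALSE) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr = lr, train_fraction = train_fraction,
                 seed = as.integer(seed), stop_when_val_dsc = stop_when_val_dsc,
                 verbose = isTRUE(verbose)),
            class = "train_cfg")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + state$eps)
  }
  list(params = params, state = state)
}

# One image's loss gradient wrt logits: d(BCE)/d(logit) = (p - y)/N for the
# sigmoid head (numerically stable combined form).
loss_and_dlogits <- function(probs, y) {
  if (length(probs) != length(y)) {
    stop("prediction and ground truth sizes differ", call. = FALSE)
  }
  N <- length(y)
  ym <- matrix(as.double(y), nrow(probs), ncol(probs))
  list(loss = bce_loss(ym, probs), dlogits = (probs - ym) / N)
}

#' Train a spatial-attention U-Net
#'
#' Mini-batch Adam on pixel-wise binary cross-entropy. Gradients only ever
#' come from training-patient images; the held-out fold is used for
#' per-epoch validation metrics and best-checkpoint selection by mean
#' validation DSC. Fully reproducible under a fixed `cfg$seed`
#' (single-threaded deterministic arithmetic).
#'
#' @param model An [sa_unet()].
#' @param pairs List of image/mask pairs (e.g. from [generate_dataset()]),
#'   already preprocessed to a common size divisible by 64.
#' @param split List with `train`/`test` patient id vectors from
#'   [patient_split()].
#' @param cfg A [train_cfg()].
#' @return An `sa_unet_fit`: list with `model` (best checkpoint),
#'   `final_model`, `history` (tibble: epoch, train_loss, val_dsc),
#'   `best_epoch`, `split`, `cfg`.
#' @export
train_unet <- function(model, pairs, split, cfg = train_cfg()) {
  pids <- vapply(pairs, function(p) p$patient_id, character(1))
  train_idx <- which(pids %in% split$train)
  val_idx <- which(pids %in% split$test)
  if (length(train_idx) == 0) stop("no training images after split", call. = FALSE)
  if (length(val_idx) == 0) stop("no validation images after split", call. = FALSE)

  params <- model$params
  state <- adam_init(params)
  history <- vector("list", cfg$epochs)
  best <- list(dsc = -Inf, params = params, epoch = 0L)

  order_seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max %/% 2, cfg$epochs))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- with_seed(order_seeds[epoch], sample(train_idx))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL
      bl <- 0
      for (i in batch) {
        m <- model; m$params <- params
        fm <- prepare_input(m, pairs[[i]]$image)
        fwd <- unet_forward_internal(m, fm, keep = TRUE)
        ld <- loss_and_dlogits(fwd$probs, pairs[[i]]$mask)
        if (!is.finite(ld$loss)) {
          stop(sprintf("non-finite loss at epoch %d (image %d); aborting", epoch, i),
               call. = FALSE)
        }
        g <- unet_backward_internal(m, fwd, ld$dlogits)
        bl <- bl + ld$loss
        acc <- if (is.null(acc)) g else mapply(`+`, acc, g, SIMPLIFY = FALSE)
      }
      acc <- lapply(acc, function(g) g / length(batch))
      upd <- adam_step(params, acc[names(params)], state, cfg$lr)
      params <- upd$params; state <- upd$state
      epoch_loss <- epoch_loss + bl
    }
    epoch_loss <- epoch_loss / length(train_idx)

    m <- model; m$params <- params
    val_dsc <- mean(vapply(val_idx, function(i) {
      probs <- unet_forward(m, pairs[[i]]$image)
      dsc(binarize(probs), pairs[[i]]$mask)
    }, numeric(1)))
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = epoch_loss,
                                       val_dsc = val_dsc)
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f  val DSC %.4f", epoch, epoch_loss, val_dsc))
    }
    if (val_dsc > best$dsc) best <- list(dsc = val_dsc, params = params, epoch = epoch)
    if (!is.null(cfg$stop_when_val_dsc) && val_dsc >= cfg$stop_when_val_dsc) break
  }

  best_model <- model; best_model$params <- best$params
  final_model <- model; final_model$params <- params
  structure(list(model = best_model, final_model = final_model,
                 history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
                 best_epoch = best$epoch, split = split, cfg = cfg),
            class = "sa_unet_fit")
}

#' @export
print.sa_unet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<sa_unet_fit> %d epoch(s); best val DSC %.4f at epoch %d\n",
              nrow(h), max(h$val_dsc), x$best_epoch))
  invisible(x)
}

#' Evaluate a model on a set of image/mask pairs
#'
#' Runs forward inference, postprocessing and the full metric suite per
#' image, then averages. Images where HD95 is undefined (empty predicted or
#' true mask) contribute `NA` there and are excluded from the HD95 mean;
#' the count of such exclusions is reported.
#'
#' @param model An `sa_unet` (or an `sa_unet_fit`, whose best model is used).
#' @param pairs List of image/mask pairs.
#' @param threshold Binarization threshold.
#' @param postprocess Apply [postprocess_mask()] (component filtering)
#'   instead of plain thresholding.
#' @param min_size Minimum component size at 512 x 512 (see
#'   [postprocess_mask()]).
#' @return An `eval_report`: list with `per_image` (tibble) and `summary`
#'   (one-row tibble of metric means), plus `hd95_excluded`.
#' @export
evaluate_run <- function(model, pairs, threshold = 0.5, postprocess = TRUE,
                         min_size = 10) {
  if (inherits(model, "sa_unet_fit")) model <- model$model
  if (length(pairs) == 0) stop("empty test set", call. = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    probs <- unet_forward(model, pairs[[i]]$image)
    pred <- if (postprocess) postprocess_mask(probs, threshold, min_size)
            else binarize(probs, threshold)
    dplyr::bind_cols(tibble::tibble(id = i, patient_id = pairs[[i]]$patient_id),
                     seg_metrics(pred, pairs[[i]]$mask, probs))
  })
  per_image <- dplyr::bind_rows(rows)
  metric_cols <- c("dsc", "precision", "recall", "accuracy", "auc", "hd95")
  summary <- dplyr::summarise(per_image,
                              dplyr::across(dplyr::all_of(metric_cols),
                                            ~ mean(.x, na.rm = TRUE)))
  structure(list(per_image = per_image, summary = summary,
                 hd95_excluded = sum(is.na(per_image$hd95))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d image(s); mean DSC %.4f, HD95 %.2f (%d excluded)\n",
              nrow(x$per_image), x$summary$dsc, x$summary$hd95, x$hd95_excluded))
  invisible(x)
}
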