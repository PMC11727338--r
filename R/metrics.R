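# Evaluation suite: pixel-level confusion counts, Dice similarity
# coefficient, precision/recall/accuracy, ROC-AUC by threshold sweep with
# trapezoidal summation, 95th-percentile Hausdorff distance over boundary
# pixels, and multi-run aggregation (mean, SD, t-based 95% CI).

#' Pixelwise confusion counts between a predicted and true mask
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return A tibble with one row: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  assert_same_shape(pred, truth, "pred and truth")
  assert_binary_mask(pred, "pred"); assert_binary_mask(truth, "truth")
  p <- as.vector(pred) == 1; t <- as.vector(truth) == 1
  tibble::tibble(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t))
}

#' Dice similarity coefficient
#'
#' `2|A.B| / (|A|+|B|)` between predicted (A) and ground-truth (B)
#' foreground sets. Convention for degenerate masks: both empty gives 1.0
#' (perfect agreement on "no lesion"), one empty gives 0.0.
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return Value in `[0, 1]`.
#' @export
dsc <- function(pred, truth) {
  assert_same_shape(pred, truth, "pred and truth")
  a <- sum(pred == 1); b <- sum(truth == 1)
  if (a + b == 0) return(1.0)
  2 * sum(pred == 1 & truth == 1) / (a + b)
}

#' Precision, recall and accuracy from confusion counts
#'
#' Zero-denominator convention: precision with no predicted positives and
#' recall with no true positives return `NA_real_` (undefined, excluded
#' from averages), matching how per-image metrics are usually pooled.
#'
#' @param counts One-row tibble/list with `tp`, `fp`, `tn`, `fn`.
#' @return Named list with `precision`, `recall`, `accuracy`.
#' @export
prf_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  list(
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    accuracy = (tp + tn) / (tp + tn + fp + fn)
  )
}

#' ROC curve from a probability map and a binary truth mask
#'
#' Sweeps all distinct predicted probabilities as thresholds (prediction
#' positive when probability >= threshold), yielding points from (0, 0) to
#' (1, 1) with nondecreasing FPR.
#'
#' @param probs Numeric matrix/vector of scores.
#' @param truth Binary matrix/vector, same length.
#' @return Tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(probs, truth) {
  p <- as.vector(probs); y <- as.vector(truth)
  if (length(p) != length(y)) stop("probs and truth must have the same length", call. = FALSE)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  if (npos == 0 || nneg == 0) {
    stop("truth contains a single class; ROC/AUC undefined", call. = FALSE)
  }
  th <- sort(unique(p), decreasing = TRUE)
  tp <- cumsum(tapply(y == 1, factor(-p, levels = sort(-th)), sum))
  fp <- cumsum(tapply(y == 0, factor(-p, levels = sort(-th)), sum))
  tibble::tibble(threshold = c(Inf, th),
                 fpr = c(0, as.numeric(fp) / nneg),
                 tpr = c(0, as.numeric(tp) / npos))
}

#' Area under the ROC curve by trapezoidal summation
#'
#' Applies the summation `sum_i (FPR_i - FPR_{i-1}) * (TPR_i + TPR_{i-1})/2`
#' over the threshold-sweep ROC curve. Equals the Mann-Whitney rank
#' statistic (with ties counted half).
#'
#' @inheritParams roc_curve
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(probs, truth) {
  rc <- roc_curve(probs, truth)
  n <- nrow(rc)
  sum((rc$fpr[-1] - rc$fpr[-n]) * (rc$tpr[-1] + rc$tpr[-n]) / 2)
}

# Boundary pixels of a binary mask: foreground pixels with at least one
# background 4-neighbour (image border counts as background). Returns an
# n x 2 matrix of (row, col) coordinates.
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  m <- matrix(0L, H + 2, W + 2)
  m[2:(H + 1), 2:(W + 1)] <- as.integer(mask == 1)
  inner <- m[2:(H + 1), 2:(W + 1)]
  nb <- m[1:H, 2:(W + 1)] + m[3:(H + 2), 2:(W + 1)] +
    m[2:(H + 1), 1:W] + m[2:(H + 1), 3:(W + 2)]
  which(inner == 1L & nb < 4L, arr.ind = TRUE)
}

#' 95th-percentile Hausdorff distance between two masks
#'
#' Boundary pixels are extracted by 4-connectivity erosion difference;
#' Euclidean distances from each boundary to the other are reduced to their
#' 95th percentiles (linear interpolation) and the maximum of the two
#' directed values is returned, making the measure symmetric.
#'
#' @param pred,truth Binary matrices of identical shape; both must be
#'   nonempty.
#' @param percentile Percentile of directed boundary distances (default 0.95).
#' @return Distance in pixels.
#' @export
hd95 <- function(pred, truth, percentile = 0.95) {
  assert_same_shape(pred, truth, "pred and truth")
  if (sum(pred == 1) == 0 || sum(truth == 1) == 0) {
    stop("hd95 is undefined for an empty mask (no boundary exists)", call. = FALSE)
  }
  a <- boundary_pixels(pred); b <- boundary_pixels(truth)
  d_ab <- cpp_directed_min_dists(a + 0, b + 0)
  d_ba <- cpp_directed_min_dists(b + 0, a + 0)
  max(quantile(d_ab, percentile, names = FALSE),
      quantile(d_ba, percentile, names = FALSE))
}

#' All segmentation metrics for one predicted/true pair
#'
#' @param pred Binary predicted mask.
#' @param truth Binary ground-truth mask.
#' @param probs Optional probability map for ROC-AUC (AUC is `NA` when
#'   omitted or when truth is single-class).
#' @return One-row tibble: `dsc`, `precision`, `recall`, `accuracy`, `auc`,
#'   `hd95` (NA when either mask is empty).
#' @export
seg_metrics <- function(pred, truth, probs = NULL) {
  cc <- confusion_counts(pred, truth)
  pr <- prf_metrics(cc)
  auc <- NA_real_
  if (!is.null(probs) && length(unique(as.vector(truth))) == 2) {
    auc <- roc_auc(probs, truth)
  }
  hd <- if (sum(pred == 1) > 0 && sum(truth == 1) > 0) hd95(pred, truth) else NA_real_
  tibble::tibble(dsc = dsc(pred, truth), precision = pr$precision,
                 recall = pr$recall, accuracy = pr$accuracy,
                 auc = auc, hd95 = hd)
}

#' Aggregate per-run metrics into mean, SD and 95% confidence interval
#'
#' Takes one row per independent run (columns = metrics) and returns, per
#' metric, the mean, sample SD, and a Student-t 95% CI half-width
#' `t(0.975, n-1) * SD / sqrt(n)`, the standard way repeated-seed results
#' are reported.
#'
#' @param runs A data frame with one row per run and one numeric column per
#'   metric (non-numeric columns are ignored).
#' @return A tibble with columns `metric`, `n`, `mean`, `sd`, `ci95`.
#' @export
aggregate_runs <- function(runs) {
  runs <- tibble::as_tibble(runs)
  runs <- runs[vapply(runs, is.numeric, logical(1))]
  if (nrow(runs) < 2) stop("aggregation requires >= 2 runs", call. = FALSE)
  long <- tidyr::pivot_longer(runs, dplyr::everything(),
                              names_to = "metric", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    ci95 = ifelse(.data$n > 1, qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n), NA_real_),
    .groups = "drop"
  )
}
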