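# Postprocessing: threshold the probability map, label connected
# components, and drop spurious small components (or keep only the largest).

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is `>=` the threshold
#' (boundary convention: ties go to foreground).
#'
#' @param probs Numeric matrix of probabilities.
#' @param threshold Value in (0, 1); default 0.5.
#' @return Integer binary matrix.
#' @export
binarize <- function(probs, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)", call. = FALSE)
  matrix(as.integer(probs >= threshold), nrow(probs), ncol(probs))
}

#' Label connected components of a binary mask
#'
#' Foreground pixels share a label iff they are connected under the chosen
#' connectivity. Labels are contiguous `1..k`; background is 0.
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8 (default 8, suited to blob-like lesions).
#' @return A `component_labeling`: list with `labels` (integer matrix) and
#'   `sizes` (pixel count per label).
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_binary_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  lab <- cpp_label_components(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                              as.integer(connectivity))
  k <- max(lab)
  structure(list(labels = lab,
                 sizes = if (k > 0) tabulate(lab[lab > 0], nbins = k) else integer(0),
                 connectivity = as.integer(connectivity)),
            class = "component_labeling")
}

#' @export
print.component_labeling <- function(x, ...) {
  cat(sprintf("<component_labeling> %d component(s), sizes [%s], %d-connectivity\n",
              length(x$sizes), paste(x$sizes, collapse = ", "), x$connectivity))
  invisible(x)
}

#' Remove components smaller than a minimum size
#'
#' Components with fewer than `min_size` pixels are dropped; all others are
#' preserved exactly. Idempotent.
#'
#' @param labeling A `component_labeling` (or a binary mask, which is
#'   labeled first with 8-connectivity).
#' @param min_size Minimum component size in pixels (>= 0; 0 is identity).
#' @return Integer binary mask.
#' @export
filter_small <- function(labeling, min_size) {
  if (min_size < 0) stop("min_size must be >= 0", call. = FALSE)
  if (!inherits(labeling, "component_labeling")) labeling <- label_components(labeling)
  keep <- which(labeling$sizes >= min_size)
  lab <- labeling$labels
  matrix(as.integer(lab %in% keep & lab > 0), nrow(lab), ncol(lab))
}

#' Full postprocessing: threshold, label, filter
#'
#' The default minimum component size of 10 px is defined at 512 x 512
#' resolution and scaled proportionally to image area for other sizes.
#' `mode = "largest"` instead keeps only the largest component.
#'
#' @param probs Probability matrix.
#' @param threshold Binarization threshold (default 0.5).
#' @param min_size Minimum component size at 512 x 512 (default 10).
#' @param connectivity 4 or 8 (default 8).
#' @param mode `"filter"` (drop small components) or `"largest"` (keep only
#'   the largest component).
#' @return Integer binary mask.
#' @export
postprocess_mask <- function(probs, threshold = 0.5, min_size = 10,
                             connectivity = 8L, mode = c("filter", "largest")) {
  mode <- match.arg(mode)
  mask <- binarize(probs, threshold)
  lab <- label_components(mask, connectivity)
  if (length(lab$sizes) == 0) return(mask)
  if (mode == "largest") {
    keep <- which.max(lab$sizes)
    return(matrix(as.integer(lab$labels == keep), nrow(mask), ncol(mask)))
  }
  scaled <- min_size * (nrow(mask) * ncol(mask)) / 512^2
  filter_small(lab, scaled)
}
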