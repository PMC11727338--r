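# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training history
#'
#' @param x An `sa_unet_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (`epoch`, `train_loss`, `val_dsc`).
#' @export
tidy.sa_unet_fit <- function(x, ...) x$history

#' One-row summary of a training run
#'
#' @param x An `sa_unet_fit`.
#' @param ... Unused.
#' @return Tibble with `epochs`, `best_epoch`, `best_val_dsc`,
#'   `final_train_loss`, `n_parameters`.
#' @export
glance.sa_unet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 best_val_dsc = max(h$val_dsc),
                 final_train_loss = h$train_loss[nrow(h)],
                 n_parameters = n_parameters(x$model))
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-image metric tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_image

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble of metric means plus `n_images`, `hd95_excluded`.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(n_images = nrow(x$per_image),
                                  hd95_excluded = x$hd95_excluded))
}

#' Plot training curves
#'
#' @param object An `sa_unet_fit`.
#' @param ... Unused.
#' @return A ggplot with training loss and validation DSC per epoch.
#' @export
autoplot.sa_unet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_dsc"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot per-image metric distributions
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot boxplot of the per-image metrics.
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image,
                              c("dsc", "precision", "recall", "accuracy", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "per-image value")
}
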