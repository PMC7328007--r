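# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# evaluation reports.

#' @export
tidy.seg_fit <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.seg_fit <- function(x, ...) {
  tibble::tibble(
    encoder = x$config$encoder,
    input_size = x$input_size,
    n_params = nn_n_params(x$model),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_dice = if (is.null(x$history)) NA_real_ else max(x$history$val_dice),
    final_val_loss = if (is.null(x$history)) NA_real_ else
      x$history$val_loss[nrow(x$history)]
  )
}

#' @export
tidy.clf_fit <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  x$history
}

#' @export
glance.clf_fit <- function(x, ...) {
  tibble::tibble(
    backbone = x$config$backbone,
    input_size = x$input_size,
    n_params = nn_n_params(x$model),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    best_val_accuracy = if (is.null(x$history)) NA_real_ else
      max(x$history$val_accuracy),
    best_val_log_loss = if (is.null(x$history)) NA_real_ else
      min(x$history$val_log_loss)
  )
}

#' @export
tidy.colony_eval <- function(x, ...) x$per_class

#' @export
glance.colony_eval <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    accuracy = x$accuracy,
    pooled_accuracy = x$pooled_accuracy
  )
}

#' @export
tidy.plate_comparison <- function(x, ...) x$plates

#' @export
glance.plate_comparison <- function(x, ...) {
  tibble::tibble(
    n_plates = nrow(x$plates),
    mean_abs_diff = x$mean_abs_diff,
    mean_signed_diff = x$mean_signed_diff
  )
}

#' @export
autoplot.seg_fit <- function(object, ...) {
  h <- tidy(object)
  h |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_dice"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Segmenter training") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.clf_fit <- function(object, ...) {
  h <- tidy(object)
  h |>
    tidyr::pivot_longer(c("train_loss", "val_log_loss", "val_accuracy"),
                        names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Classifier training") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.colony_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "grey20") +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::scale_y_discrete(limits = rev(colony_phenotypes())) +
    ggplot2::labs(title = "Colony classification confusion matrix",
                  x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pipeline_result <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$plate_id, y = .data$pct_non_white)) +
    ggplot2::geom_col(fill = "#c0392b") +
    ggplot2::labs(x = NULL, y = "% non-white colonies",
                  title = "Predicted non-white percentage per plate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.plate_comparison <- function(object, ...) {
  ggplot2::ggplot(object$plates,
                  ggplot2::aes(x = .data$pct_true, y = .data$pct_predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::labs(x = "true % non-white", y = "predicted % non-white",
                  title = "Predicted vs true non-white percentage") +
    ggplot2::theme_minimal()
}
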