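#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model: the per-epoch training loss trace
#'
#' @param x A `taste_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.taste_fit <- function(x, ...) x$loss_trace

#' One-row summary of a fitted model
#'
#' @param x A `taste_fit`.
#' @param ... Unused.
#' @return Tibble with epochs trained, final loss and parameter count.
#' @export
glance.taste_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$loss_trace),
                 final_loss = x$loss_trace$loss[max(1, nrow(x$loss_trace))],
                 n_parameters = count_parameters(x$model),
                 learning_rate = x$config$learning_rate,
                 batch_size = x$config$batch_size)
}

#' Tidy evaluation metrics: one row per class
#'
#' @param x A `taste_metrics`.
#' @param ... Unused.
#' @return Tibble with class, one-vs-rest tallies, precision and recall.
#' @export
tidy.taste_metrics <- function(x, ...) x$per_class

#' One-row summary of evaluation metrics
#'
#' @param x A `taste_metrics`.
#' @param ... Unused.
#' @export
glance.taste_metrics <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 precision_macro = x$precision_macro,
                 recall_macro = x$recall_macro)
}

#' Tidy a cross-validation run: one row per fold
#'
#' @param x A `taste_cv`.
#' @param ... Unused.
#' @export
tidy.taste_cv <- function(x, ...) x$folds

#' One-row cross-validation summary (mean +/- sd across folds)
#'
#' @param x A `taste_cv`.
#' @param ... Unused.
#' @export
glance.taste_cv <- function(x, ...) {
  f <- x$folds
  tibble::tibble(n_folds = nrow(f),
                 accuracy_mean = mean(f$accuracy),
                 accuracy_sd = stats::sd(f$accuracy),
                 precision_mean = mean(f$precision_macro),
                 precision_sd = stats::sd(f$precision_macro),
                 recall_mean = mean(f$recall_macro),
                 recall_sd = stats::sd(f$recall_macro))
}

#' Training-loss curve
#'
#' @param object A `taste_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heat map
#'
#' @param object A `taste_metrics`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "grey20") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Fold accuracies across a cross-validation run
#'
#' @param object A `taste_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(factor(.data$fold),
                                             .data$accuracy)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::labs(x = "fold", y = "validation accuracy") +
    ggplot2::theme_minimal()
}

#' Ablation summary plot (mean +/- sd accuracy per configuration)
#'
#' @param object A `taste_ablation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.taste_ablation <- function(object, ...) {
  df <- as.data.frame(object)
  df$config_id <- factor(df$config_id, levels = df$config_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$config_id, .data$accuracy_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy_mean - .data$accuracy_sd,
      ymax = .data$accuracy_mean + .data$accuracy_sd), colour = "#2c7fb8") +
    ggplot2::labs(x = NULL, y = "CV accuracy (mean +/- sd)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
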