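# ggplot2 displays for fitted objects and metric reports.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Top-k accuracy curve of a cross-validation report
#'
#' Per-fold top-k accuracies (thin lines) with the fold mean (bold), the
#' curve used to judge how deep a screening list must go to contain the true
#' photocatalyst.
#'
#' @param object a `pc_metrics` from [cross_validate()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pc_metrics
#' @export
autoplot.pc_metrics <- function(object, ...) {
  folds <- tidyr::unnest(
    dplyr::mutate(object$per_fold,
                  topk = purrr::map(.data$topk, ~tibble::tibble(
                    k = seq_along(.x), accuracy = .x))),
    "topk")
  mean_df <- tibble::tibble(k = seq_along(object$topk_mean),
                            accuracy = object$topk_mean)
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$fold), alpha = 0.35) +
    ggplot2::geom_line(data = mean_df, linewidth = 1) +
    ggplot2::geom_point(data = mean_df) +
    ggplot2::labs(x = "k (ranking depth)", y = "top-k accuracy",
                  title = sprintf("%d-fold cross-validated top-k accuracy",
                                  object$k)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a fitted MLP
#'
#' @param object a `pc_mlp`.
#' @param ... unused.
#' @method autoplot pc_mlp
#' @export
autoplot.pc_mlp <- function(object, ...) {
  ggplot2::ggplot(object$training_report,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy",
                  title = "MLP training loss") +
    ggplot2::theme_minimal()
}

#' Pretraining curve of a masked language model
#'
#' Held-out masked-token loss by epoch, starting from the untrained
#' (epoch-0) baseline.
#'
#' @param object a `pc_lm`.
#' @param ... unused.
#' @method autoplot pc_lm
#' @export
autoplot.pc_lm <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$epoch, y = .data$holdout_loss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "held-out masked-token loss",
                  title = "Masked-LM pretraining") +
    ggplot2::theme_minimal()
}

#' Class-frequency bar chart of a labeled record set
#'
#' Visualizes the Zipf-like catalyst imbalance of a corpus.
#'
#' @param data record tibble with a `catalyst` column.
#' @return a ggplot object.
#' @export
plot_class_distribution <- function(data) {
  counts <- dplyr::arrange(dplyr::count(data, .data$catalyst), dplyr::desc(.data$n))
  counts$catalyst <- factor(counts$catalyst, levels = counts$catalyst)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$catalyst, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "records",
                  title = "Catalyst label frequencies") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
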