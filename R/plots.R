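#' Plot ROC or precision-recall curve for a metrics report
#'
#' @param object An `iani_metrics` report from [evaluate_scores()].
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.iani_metrics <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  if (type == "roc") {
    dat <- attr(object, "roc_curve")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dotted", colour = "grey50") +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC curve (AUC = %.3f)", object$roc_auc)
      ) +
      ggplot2::theme_minimal()
  } else {
    dat <- attr(object, "pr_curve")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall curve (AUPRC = %.3f)",
                        object$auprc)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot the test-set ROC or PR curve of a fitted ensemble
#'
#' @param object An `iani_ensemble`.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.iani_ensemble <- function(object, type = c("roc", "pr"), ...) {
  autoplot.iani_metrics(object$metrics, type = type)
}

#' Plot the outdegree distribution with the hub threshold
#'
#' @param object A `hub_set`.
#' @param log_x Log-scale the degree axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.hub_set <- function(object, log_x = TRUE, ...) {
  all_deg <- attr(object, "all_degrees")
  p <- ggplot2::ggplot(all_deg, ggplot2::aes(x = .data$outdegree)) +
    ggplot2::geom_histogram(bins = 50, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(
      x = "Outdegree", y = "Genes",
      title = sprintf("Hub threshold mu + 2 sigma = %.1f (%d hubs)",
                      attr(object, "threshold"), nrow(object))
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a degree-matched null distribution with the observed overlap
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot, one facet per reference set.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(object$overlaps,
                  ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60",
                            colour = "white") +
    ggplot2::geom_vline(
      data = object$results,
      ggplot2::aes(xintercept = .data$observed), colour = "red"
    ) +
    ggplot2::facet_wrap(~reference, scales = "free") +
    ggplot2::labs(
      x = "Overlap proportion of degree-matched null sets", y = "Replicates",
      title = "Observed overlap (red) vs degree-matched null"
    ) +
    ggplot2::theme_minimal()
}

#' Gradient-boosting feature importances of a fitted ensemble
#'
#' Gain-based importances (summing to 1) of the gradient-boosting member,
#' the conventional view of which topology features drive prediction.
#'
#' @param model An `iani_ensemble`.
#' @return A ggplot bar chart.
#' @export
plot_feature_importance <- function(model) {
  stopifnot(inherits(model, "iani_ensemble"))
  imp <- xgboost::xgb.importance(model = model$learners$gradient_boosting$fit)
  dat <- tibble::tibble(
    feature = imp$Feature,
    importance = imp$Gain
  )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$importance),
    y = .data$importance
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Gain importance",
                  title = "Gradient-boosting feature importance") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
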