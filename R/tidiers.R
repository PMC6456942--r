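#' Tidy a cross-validation result into per-marker metrics
#'
#' @param x An `epideep_cv` from [run_cv()].
#' @param ... Unused.
#' @return The [cv_metrics()] tibble: one row per marker with one-vs-rest
#'   auROC/auPRC over the out-of-fold predictions.
#' @method tidy epideep_cv
#' @export
tidy.epideep_cv <- function(x, ...) {
  cv_metrics(x)
}

#' One-row summary of a cross-validation result
#'
#' @param x An `epideep_cv`.
#' @param ... Unused.
#' @return Tibble with problem size, fold count, epochs actually trained and
#'   mean per-marker metrics.
#' @method glance epideep_cv
#' @export
glance.epideep_cv <- function(x, ...) {
  m <- cv_metrics(x)
  tibble(epigenome = x$epigenome_id %||% NA_character_,
         n_examples = nrow(x$oof),
         n_markers = length(x$markers),
         folds = x$config$folds,
         mode = x$spec$mode,
         total_epochs = sum(vapply(x$models, function(mm) {
           nrow(mm$training_log)
         }, numeric(1))),
         mean_auroc = mean(m$auroc, na.rm = TRUE),
         mean_auprc = mean(m$auprc, na.rm = TRUE))
}

#' Plot per-marker out-of-fold metrics of a cross-validation result
#'
#' @param object An `epideep_cv`.
#' @param ... Unused.
#' @return A ggplot bar chart of auROC and auPRC per marker.
#' @method autoplot epideep_cv
#' @export
autoplot.epideep_cv <- function(object, ...) {
  m <- cv_metrics(object)
  long <- tidyr::pivot_longer(m[, c("marker", "auroc", "auprc")],
                              c("auroc", "auprc"), names_to = "metric",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "out-of-fold metric",
                  title = sprintf("one-vs-rest performance (%s, %d-fold CV)",
                                  object$spec$mode, object$config$folds)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-epoch training history of a trained model
#'
#' @param model An `epideep_model` with a training log.
#' @return A ggplot of train and holdout loss per epoch.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$training_log)) ed_stop("model has no training log", "config")
  long <- tidyr::pivot_longer(model$training_log,
                              c("train_loss", "holdout_loss"),
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "multi-label cross entropy") +
    ggplot2::theme_minimal()
}
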