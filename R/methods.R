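#' Tidy a LOPO result
#'
#' Per-lesion out-of-fold predictions as a tibble.
#'
#' @param x A `lopo_result` from [fit_lopo()].
#' @param ... Unused.
#' @return Tibble: `patient_id`, `lesion_id`, `label`, `oof_score`.
#' @exportS3Method generics::tidy
tidy.lopo_result <- function(x, ...) {
  x$predictions
}

#' Glance at a LOPO result
#'
#' One-row model summary.
#'
#' @param x A `lopo_result` from [fit_lopo()].
#' @param ... Unused.
#' @return One-row tibble: task, lesion/patient counts, mean and range of
#'   per-fold training AUCs, pooled validation AUC with 95% CI.
#' @exportS3Method generics::glance
glance.lopo_result <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_patients = nrow(x$folds),
    n_lesions = nrow(x$predictions),
    n_positive = sum(x$predictions$label),
    train_auc_mean = mean(x$folds$train_auc, na.rm = TRUE),
    train_auc_min = min(x$folds$train_auc, na.rm = TRUE),
    train_auc_max = max(x$folds$train_auc, na.rm = TRUE),
    valid_auc = x$pooled$auc,
    valid_auc_ci_lower = x$pooled$ci_lower,
    valid_auc_ci_upper = x$pooled$ci_upper
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC plot for a LOPO result
#'
#' Plots the pooled validation ROC curve (dashed) together with the ROC of
#' the best and worst training folds by out-of-bag AUC (solid), the standard
#' presentation for leave-one-patient-out forests in this pipeline.
#'
#' @param object A `lopo_result` from [fit_lopo()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lopo_result <- function(object, ...) {
  roc_points <- function(scores, labels) {
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tibble::tibble(
      fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)),
      tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
    )
  }
  ok <- which(!is.na(object$folds$train_auc))
  best <- ok[which.max(object$folds$train_auc[ok])]
  worst <- ok[which.min(object$folds$train_auc[ok])]
  curves <- dplyr::bind_rows(
    roc_points(object$train_curves[[best]]$scores,
               object$train_curves[[best]]$labels) |>
      dplyr::mutate(set = sprintf("best training fold (AUC %.2f)",
                                  object$folds$train_auc[best])),
    roc_points(object$train_curves[[worst]]$scores,
               object$train_curves[[worst]]$labels) |>
      dplyr::mutate(set = sprintf("worst training fold (AUC %.2f)",
                                  object$folds$train_auc[worst])),
    object$pooled$curve |>
      dplyr::select("fpr", "tpr") |>
      dplyr::mutate(set = sprintf("pooled validation (AUC %.2f)",
                                  object$pooled$auc))
  )
  curves$linetype <- ifelse(grepl("validation", curves$set), "dashed", "solid")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                       colour = .data$set,
                                       linetype = .data$linetype)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey80") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_linetype_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL,
                  title = sprintf("%s task: LOPO random forest ROC", object$task)) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of per-lesion volume change
#'
#' Per-patient spread of lesion response: one point per lesion, patients on
#' the x axis, percent volume change on the y axis, with the PR cut-off
#' marked.
#'
#' @param outcomes Outcome tibble from [label_responses()].
#' @param pr_threshold PR cut-off to mark (default 65% decrease).
#' @return A ggplot object.
#' @export
plot_response_spread <- function(outcomes, pr_threshold = 65) {
  ggplot2::ggplot(outcomes,
                  ggplot2::aes(x = .data$patient_id, y = .data$pct_change)) +
    ggplot2::geom_hline(yintercept = -pr_threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$label_pr),
                         width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::labs(x = "Patient", y = "Volume change (%)",
                  colour = sprintf("> %g%% decrease", pr_threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
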