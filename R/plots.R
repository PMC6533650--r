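## ggplot2 graphics for ROC curves and score distributions.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `psc_roc` object from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.psc_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf(
        "ROC, %s%s: AUC = %.3f", object$outcome,
        if (is.na(object$model)) "" else paste0(" (", object$model, ")"),
        object$auc
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot ROC curves for several models
#'
#' @param cohort A labelled cohort.
#' @param models Model names to draw.
#' @param outcome `"pca"` or `"cs_pca"`.
#' @return A ggplot with one curve per model, AUC in the legend.
#' @export
plot_roc_models <- function(cohort, models = c("baseline", "model6", "model13"),
                            outcome = c("pca", "cs_pca")) {
  outcome <- match.arg(outcome)
  profiles <- profile_cohort(cohort)
  curves <- purrr::map_dfr(models, function(m) {
    r <- roc_curve(score_cohort(profiles, m), outcome)
    dplyr::mutate(r$points, model = sprintf("%s (AUC %.3f)", m, r$auc))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      colour = NULL, title = paste("ROC curves,", outcome)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot score distributions by Gleason group
#'
#' @param scored A scored cohort from [score_cohort()].
#' @return A ggplot boxplot of score against the four-tier Gleason group.
#' @export
plot_group_scores <- function(scored) {
  model <- attr(scored, "model")$name %||% "score"
  ggplot2::ggplot(
    scored,
    ggplot2::aes(factor(.data$gs_group), .data$score)
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.8) +
    ggplot2::labs(
      x = "Gleason group (1 = benign)",
      y = paste(model, "score"),
      title = "Accumulating score by Gleason group"
    ) +
    ggplot2::theme_minimal()
}
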