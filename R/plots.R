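#' Plot an incremental-feature-selection curve
#'
#' LOOCV AUC against panel size, with the selected panel marked.
#'
#' @param object an `exlr_signature`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot exlr_signature
#' @export
autoplot.exlr_signature <- function(object, ...) {
  curve <- object$ifs_curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$loocv_auc)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_vline(xintercept = object$selected_k,
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "Number of top-ranked genes",
                  y = "LOOCV AUC",
                  title = sprintf("IFS curve (selected k = %d)",
                                  object$selected_k)) +
    ggplot2::theme_minimal()
}

#' ROC curve for scores against labels
#'
#' @param scores decision scores.
#' @param labels class labels (TRUE = case).
#' @param title plot title.
#' @return a ggplot.
#' @export
plot_roc <- function(scores, labels, title = "ROC") {
  labels <- as_binary_labels(labels, length(scores))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  df <- tibble(
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("%s (AUC = %.3f)", title,
                                  roc_auc(scores, labels))) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot for one or two groups
#'
#' @param object an `exlr_km` tibble from [km_estimate()], or a named list
#'   of them for overlaying groups.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot exlr_km
#' @export
autoplot.exlr_km <- function(object, ...) {
  plot_km(list(all = object))
}

#' @rdname autoplot.exlr_km
#' @param curves named list of `exlr_km` tibbles.
#' @export
plot_km <- function(curves) {
  df <- dplyr::bind_rows(
    purrr::imap(curves, function(km, nm) {
      tibble(group = nm,
             time = c(0, km$time),
             survival = c(1, km$survival))
    }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}
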