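#' Logistic (Platt-style) calibration of decision scores
#'
#' Fits `P(case | s) = 1 / (1 + exp(-(a + b s)))` by logistic regression of
#' the class labels on held-out (LOOCV) decision scores, so probabilities
#' are calibrated without reusing training predictions. Degenerate inputs
#' (perfectly separated scores) fall back to a steep but finite sigmoid.
#'
#' @param scores decision scores (held out, e.g. from [loocv_scores()]).
#' @param labels class labels (TRUE = case).
#' @return list with coefficients `a` (intercept) and `b` (slope, >= 0).
#' @export
fit_platt <- function(scores, labels) {
  labels <- as_binary_labels(labels, length(scores))
  fit <- suppressWarnings(
    glm(labels ~ scores, family = binomial())
  )
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  if (!is.finite(a) || !is.finite(b) || b < 0) {
    # separation or inverted fit: anchor a monotone sigmoid at the midpoint
    mid <- (max(scores[!labels]) + min(scores[labels])) / 2
    b <- 10 / max(stats::sd(scores), .Machine$double.eps)
    a <- -b * mid
  }
  list(a = a, b = b)
}

platt_probability <- function(scores, platt) {
  1 / (1 + exp(-(platt$a + platt$b * scores)))
}

#' Apply a frozen signature model to new samples
#'
#' Computes the SVM decision score for every sample using the stored
#' feature panel, scaling statistics and support vectors — nothing is
#' refit — plus the calibrated probability of being a case.
#'
#' @param object an `exlr_signature` from [ifs_select()].
#' @param log_expr an [exlr_matrix()] with unit `"log2tpm"` containing every
#'   model feature.
#' @param ... unused.
#' @return a tibble with `sample_id`, `score`, `probability`.
#' @export
predict.exlr_signature <- function(object, log_expr, ...) {
  assert_unit(log_expr, "log2tpm")
  missing <- setdiff(object$features, rownames(log_expr))
  if (length(missing)) {
    abort(paste0("matrix is missing model feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  x <- t(unclass(log_expr)[object$features, , drop = FALSE])
  scores <- svm_decision(object$model,
                         scale_with(x, object$center, object$scale))
  tibble(
    sample_id = colnames(log_expr),
    score = scores,
    probability = platt_probability(scores, object$platt)
  )
}

#' Choose a decision threshold from scores and labels
#'
#' `"youden"` maximizes sensitivity + specificity - 1 over candidate cuts
#' (midpoints between consecutive distinct scores); ties take the lowest
#' threshold. A sample is called a case when its score exceeds the
#' threshold. `"fixed"` returns `fixed` unchanged.
#'
#' @param scores decision scores.
#' @param labels class labels (TRUE = case).
#' @param method `"youden"` or `"fixed"`.
#' @param fixed threshold used when `method = "fixed"`.
#' @return a single threshold value.
#' @export
choose_threshold <- function(scores, labels, method = c("youden", "fixed"),
                             fixed = 0) {
  method <- match.arg(method)
  if (method == "fixed") return(fixed)
  labels <- as_binary_labels(labels, length(scores))
  if (!any(labels) || all(labels)) abort("both classes must be present.")
  s <- sort(unique(scores))
  if (length(s) == 1) return(s)  # degenerate: J = 0 everywhere
  cuts <- (head(s, -1) + s[-1]) / 2
  j <- vapply(cuts, function(t) {
    mean(scores[labels] > t) + mean(scores[!labels] <= t) - 1
  }, numeric(1))
  cuts[which.max(j)]  # first max = lowest threshold
}

#' Evaluate classification scores against labels
#'
#' Calls a sample a case when `score > threshold` and reports sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), accuracy, AUC ([roc_auc()]) and a
#' 95% confidence interval for the AUC by DeLong's method (default) or a
#' stratified bootstrap.
#'
#' @param scores decision scores.
#' @param labels class labels (TRUE = case).
#' @param threshold decision threshold (frozen from training).
#' @param cohort_name label recorded in the report.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_reps,boot_seed bootstrap replicates and seed.
#' @return one-row tibble: `cohort_name`, `auc`, `ci_low`, `ci_high`,
#'   `sensitivity`, `specificity`, `accuracy`, `n_case`, `n_control`,
#'   `threshold`.
#' @export
evaluate_classifier <- function(scores, labels, threshold,
                                cohort_name = "cohort",
                                ci_method = c("delong", "bootstrap"),
                                boot_reps = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  labels <- as_binary_labels(labels, length(scores))
  if (!any(labels) || all(labels)) abort("both classes must be present.")
  pred <- scores > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  auc <- roc_auc(scores, labels)
  ci <- if (ci_method == "delong") {
    delong_ci(scores, labels)
  } else {
    bootstrap_auc_ci(scores, labels, reps = boot_reps, seed = boot_seed)
  }
  tibble(
    cohort_name = cohort_name,
    auc = auc,
    ci_low = ci[1], ci_high = ci[2],
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(scores),
    n_case = sum(labels), n_control = sum(!labels),
    threshold = threshold
  )
}

# DeLong (1988) variance of the AUC via placement values.
delong_ci <- function(scores, labels, level = 0.95) {
  pos <- scores[labels]
  neg <- scores[!labels]
  m <- length(pos); n <- length(neg)
  # placement of each positive against all negatives and vice versa
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  auc <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - level) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

bootstrap_auc_ci <- function(scores, labels, reps = 2000, seed = 1L,
                             level = 0.95) {
  idx_pos <- which(labels); idx_neg <- which(!labels)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      ip <- sample(idx_pos, replace = TRUE)
      ineg <- sample(idx_neg, replace = TRUE)
      roc_auc(c(scores[ip], scores[ineg]),
              c(rep(TRUE, length(ip)), rep(FALSE, length(ineg))))
    }, numeric(1))
  })
  unname(quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Evaluate a frozen signature on cohort subgroups
#'
#' Each plan entry defines a case filter and a control filter over the
#' design table (expressions on its columns, e.g.
#' `cohort == "CRC" & stage %in% c("I", "II")`). The stored model and
#' threshold are applied unchanged; a report row is produced per subgroup.
#' Subgroups with an empty side are skipped with a warning; overlapping
#' case/control selections are an error.
#'
#' @param signature an `exlr_signature`.
#' @param log_expr an [exlr_matrix()] with unit `"log2tpm"`.
#' @param design design tibble covering the matrix samples.
#' @param plan list of entries from [subgroup()].
#' @param ... passed to [evaluate_classifier()].
#' @return tibble of evaluation reports, one row per realized subgroup.
#' @export
evaluate_subgroups <- function(signature, log_expr, design, plan, ...) {
  design <- validate_design(design)
  joined <- join_design(log_expr, design)
  preds <- predict(signature, joined$matrix)
  out <- purrr::map(plan, function(sg) {
    case_ids <- joined$design$sample_id[
      rlang::eval_tidy(sg$case, data = joined$design)]
    ctrl_ids <- joined$design$sample_id[
      rlang::eval_tidy(sg$control, data = joined$design)]
    overlap <- intersect(case_ids, ctrl_ids)
    if (length(overlap)) {
      abort(sprintf("subgroup '%s': case and control filters overlap.",
                    sg$name))
    }
    if (!length(case_ids) || !length(ctrl_ids)) {
      warn(sprintf("subgroup '%s' skipped: empty case or control set.",
                   sg$name))
      return(NULL)
    }
    ids <- c(case_ids, ctrl_ids)
    sc <- preds$score[match(ids, preds$sample_id)]
    lab <- c(rep(TRUE, length(case_ids)), rep(FALSE, length(ctrl_ids)))
    evaluate_classifier(sc, lab, signature$threshold,
                        cohort_name = sg$name, ...)
  })
  dplyr::bind_rows(out)
}

#' Define a subgroup for [evaluate_subgroups()]
#'
#' @param name report label, e.g. "Stage I/II CRC vs. healthy".
#' @param case,control filter expressions over design columns.
#' @return a plan entry.
#' @export
subgroup <- function(name, case, control) {
  list(name = name, case = enquo(case), control = enquo(control))
}
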