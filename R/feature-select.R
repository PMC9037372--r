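#' Three-state discretization of expression for mutual information
#'
#' Classic mRMR preprocessing: per gene, values below
#' \eqn{\mu - \alpha\sigma} code to -1, above \eqn{\mu + \alpha\sigma} to +1,
#' else 0, with \eqn{\mu,\sigma} the gene's mean and standard deviation over
#' the given samples. Zero-variance genes code to all zeros.
#'
#' @param log_expr an [exlr_matrix()] with unit `"log2tpm"`; >= 2 samples.
#' @param alpha width of the neutral band in standard deviations.
#' @return integer matrix with the same dimnames and values in {-1, 0, 1}.
#' @export
discretize_expression <- function(log_expr, alpha = 1.0) {
  assert_unit(log_expr, "log2tpm")
  if (ncol(log_expr) < 2) abort("discretization needs >= 2 samples.")
  if (alpha <= 0) abort("alpha must be positive.")
  x <- unclass(log_expr)
  mu <- rowMeans(x)
  # population (n-denominator) sigma: the band is a property of the observed
  # profile, not an estimate of a wider population
  sigma <- sqrt(rowMeans((x - mu)^2))
  lo <- mu - alpha * sigma
  hi <- mu + alpha * sigma
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  out[x < lo] <- -1L
  out[x > hi] <- 1L
  out[sigma == 0, ] <- 0L
  out
}

#' Plug-in mutual information between two discrete vectors (bits)
#'
#' \eqn{I(X;Y) = \sum_{x,y} \hat p(x,y) \log_2 \frac{\hat p(x,y)}
#' {\hat p(x)\hat p(y)}} with empirical frequencies; empty cells
#' contribute zero.
#'
#' @param x,y equal-length discrete vectors (any atomic type).
#' @return mutual information in bits (non-negative up to rounding).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  if (!length(x)) abort("empty vectors.")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' mRMR feature ranking under the MIQ criterion
#'
#' Greedy minimum-redundancy maximum-relevance ranking of candidate genes
#' against a binary class label. Relevance of gene *f* is the mutual
#' information \eqn{I(f; c)} with the class; redundancy is the mean mutual
#' information with the genes already selected. The MIQ (mutual-information
#' quotient) score of a candidate at each step is
#' \eqn{I(f;c) / \max(\bar I(f; S), \epsilon)}; the first pick maximizes
#' relevance alone. Ties break on gene ID, so the ranking is deterministic
#' and invariant to candidate input order.
#'
#' @param disc discretized matrix from [discretize_expression()].
#' @param labels logical or 0/1 class vector over the matrix samples.
#' @param candidates gene IDs to rank (subset of the matrix rows).
#' @param eps floor for the redundancy denominator.
#' @return a tibble with `rank`, `gene_id`, `score` (MIQ score at
#'   selection), `relevance`.
#' @export
mrmr_rank_miq <- function(disc, labels, candidates = rownames(disc),
                          eps = 1e-12) {
  labels <- as_binary_labels(labels, ncol(disc))
  candidates <- as.character(candidates)
  if (!length(candidates)) abort("no candidate genes.")
  missing <- setdiff(candidates, rownames(disc))
  if (length(missing)) {
    abort(paste0("candidates absent from matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  candidates <- sort(unique(candidates))  # order-invariance + tiebreak
  relevance <- vapply(candidates,
                      function(g) mutual_information(disc[g, ], labels),
                      numeric(1))
  k <- length(candidates)
  selected <- character(0)
  scores <- numeric(k)
  # cache pairwise MI with already-selected genes as we go
  red_sum <- setNames(numeric(k), candidates)
  for (step in seq_len(k)) {
    remaining <- setdiff(candidates, selected)
    if (step == 1) {
      sc <- relevance[remaining]
    } else {
      sc <- relevance[remaining] / pmax(red_sum[remaining] / (step - 1), eps)
    }
    pick <- remaining[which.max(sc)]  # candidates sorted => ID tiebreak
    selected[step] <- pick
    scores[step] <- sc[[pick]]
    rest <- setdiff(remaining, pick)
    if (length(rest)) {
      red_sum[rest] <- red_sum[rest] + vapply(
        rest, function(g) mutual_information(disc[g, ], disc[pick, ]),
        numeric(1))
    }
  }
  tibble(rank = seq_len(k), gene_id = selected, score = scores,
         relevance = unname(relevance[selected]))
}

# --- SVM plumbing -----------------------------------------------------------

default_svm_params <- function(kernel = c("linear", "radial"), cost = 1,
                               class_weights = TRUE) {
  kernel <- match.arg(kernel)
  list(kernel = kernel, cost = cost, class_weights = class_weights)
}

# z-scale columns of a samples x features matrix with given stats;
# constant features get scale 1 so they map to exactly zero
scale_with <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

# train an SVM on samples x features matrix; returns model + orientation
fit_svm <- function(x, y, params) {
  yf <- factor(ifelse(y, "case", "control"), levels = c("control", "case"))
  cw <- if (isTRUE(params$class_weights)) {
    w <- length(yf) / (2 * table(yf))
    setNames(as.numeric(w), names(w))
  } else NULL
  e1071::svm(x = x, y = yf, kernel = params$kernel, cost = params$cost,
             scale = FALSE, class.weights = cw, probability = FALSE)
}

# decision values oriented so that larger = more case-like
svm_decision <- function(model, x) {
  pred <- predict(model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  sgn <- if (colnames(dv)[1] == "case/control") 1 else -1
  as.numeric(dv[, 1]) * sgn
}

#' Leave-one-out cross-validated SVM decision scores
#'
#' For each sample, trains an SVM on all other samples (restricted to the
#' given feature genes, each feature z-scaled with the training fold's mean
#' and standard deviation) and records the held-out sample's signed decision
#' value, oriented so that positive means case-like. Inverse-frequency class
#' weights are applied by default to offset case/control imbalance.
#'
#' @param log_expr an [exlr_matrix()] with unit `"log2tpm"`.
#' @param labels logical or 0/1 class vector (TRUE = case); >= 2 per class.
#' @param features gene IDs used as predictors.
#' @param svm_params list from [default_svm_params()].
#' @return numeric vector of decision scores, one per sample, named.
#' @export
loocv_scores <- function(log_expr, labels, features,
                         svm_params = default_svm_params()) {
  assert_unit(log_expr, "log2tpm")
  labels <- as_binary_labels(labels, ncol(log_expr))
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("need >= 2 samples per class for LOOCV.")
  }
  if (!length(features)) abort("empty feature list.")
  missing <- setdiff(features, rownames(log_expr))
  if (length(missing)) {
    abort(paste0("features absent from matrix: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- t(unclass(log_expr)[features, , drop = FALSE])  # samples x features
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- labels[-i]
    if (all(ytr) || !any(ytr)) abort("a LOOCV fold contains one class only.")
    ctr <- colMeans(xtr)
    sca <- apply(xtr, 2, sd)
    model <- fit_svm(scale_with(xtr, ctr, sca), ytr, svm_params)
    out[i] <- svm_decision(model, scale_with(x[i, , drop = FALSE], ctr, sca))
  }
  setNames(out, rownames(x))
}

#' Area under the ROC curve by the rank statistic
#'
#' \eqn{AUC = P(S_{case} > S_{control}) + \frac12 P(S_{case} = S_{control})},
#' computed from the Wilcoxon rank sum with midranks, so ties receive half
#' credit exactly.
#'
#' @param scores numeric decision scores.
#' @param labels logical or 0/1 vector; `TRUE` = case.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_binary_labels(labels, length(scores))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Incremental feature selection over an mRMR ranking
#'
#' Evaluates nested feature sets: the top-1 ranked gene, top-2, ... top-K,
#' each scored by the AUC of leave-one-out cross-validated SVM decision
#' values on the training samples. The selected panel is the smallest k
#' attaining the maximum AUC (parsimony on ties). The returned signature
#' model is an SVM retrained on all training samples with the selected
#' genes, together with the feature scaling statistics, a logistic (Platt)
#' calibration of LOOCV scores to probabilities, and a Youden-J decision
#' threshold — all frozen for later cohorts.
#'
#' @param ranking tibble from [mrmr_rank_miq()] (or any tibble with
#'   `gene_id` in rank order).
#' @param log_expr training [exlr_matrix()] with unit `"log2tpm"`.
#' @param labels training class labels (TRUE = case).
#' @param k_max largest panel size to evaluate (default: full ranking).
#' @param svm_params list from [default_svm_params()].
#' @return an object of class `exlr_signature` with elements `features`,
#'   `ifs_curve` (tibble `k`, `loocv_auc`), `selected_k`, `model`, `center`,
#'   `scale`, `platt`, `threshold`, `svm_params`, `loocv_scores`.
#' @export
ifs_select <- function(ranking, log_expr, labels, k_max = nrow(ranking),
                       svm_params = default_svm_params()) {
  if (!"gene_id" %in% names(ranking)) abort("ranking needs a gene_id column.")
  if (k_max < 1 || k_max > nrow(ranking)) {
    abort("k_max must be between 1 and the ranking length.")
  }
  labels <- as_binary_labels(labels, ncol(log_expr))
  genes <- ranking$gene_id
  auc <- numeric(k_max)
  score_list <- vector("list", k_max)
  for (k in seq_len(k_max)) {
    score_list[[k]] <- loocv_scores(log_expr, labels, genes[seq_len(k)],
                                    svm_params)
    auc[k] <- roc_auc(score_list[[k]], labels)
  }
  selected_k <- which.max(auc)  # first max = smallest k
  features <- genes[seq_len(selected_k)]
  cv_scores <- score_list[[selected_k]]

  x <- t(unclass(log_expr)[features, , drop = FALSE])
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  model <- fit_svm(scale_with(x, center, scl), labels, svm_params)
  platt <- fit_platt(cv_scores, labels)
  threshold <- choose_threshold(cv_scores, labels, method = "youden")

  structure(
    list(
      features = features,
      ifs_curve = tibble(k = seq_len(k_max), loocv_auc = auc),
      selected_k = selected_k,
      model = model,
      center = center,
      scale = scl,
      platt = platt,
      threshold = threshold,
      svm_params = svm_params,
      loocv_scores = cv_scores,
      train_auc = auc[selected_k]
    ),
    class = "exlr_signature"
  )
}

#' @export
print.exlr_signature <- function(x, ...) {
  cat(sprintf(
    "<exlr_signature> %d-gene panel (LOOCV AUC %.3f), %s kernel, threshold %.3f\n",
    length(x$features), x$train_auc, x$svm_params$kernel, x$threshold))
  cat("features:", paste(head(x$features, 10), collapse = ", "),
      if (length(x$features) > 10) "..." else "", "\n")
  invisible(x)
}

#' @rdname ifs_select
#' @param x,object an `exlr_signature`.
#' @param ... unused.
#' @method tidy exlr_signature
#' @export
tidy.exlr_signature <- function(x, ...) {
  tibble(rank = seq_along(x$features), gene_id = x$features,
         weight_center = unname(x$center), weight_scale = unname(x$scale))
}

#' @rdname ifs_select
#' @method glance exlr_signature
#' @export
glance.exlr_signature <- function(x, ...) {
  tibble(n_features = length(x$features), selected_k = x$selected_k,
         train_loocv_auc = x$train_auc, threshold = x$threshold,
         kernel = x$svm_params$kernel, cost = x$svm_params$cost)
}

#' Serialize a signature model to JSON
#'
#' Stores the ranked feature list, kernel settings, per-feature scaling,
#' support vectors and coefficients, calibration coefficients and the
#' decision threshold, so a panel can be shipped and audited as plain text.
#'
#' @param signature an `exlr_signature`.
#' @param path output path.
#' @export
write_signature_json <- function(signature, path) {
  m <- signature$model
  payload <- list(
    features = signature$features,
    kernel = signature$svm_params$kernel,
    cost = signature$svm_params$cost,
    center = as.list(signature$center),
    scale = as.list(signature$scale),
    support_vectors = unclass(m$SV),
    coefs = as.numeric(m$coefs),
    rho = as.numeric(m$rho),
    gamma = as.numeric(m$gamma),
    platt = signature$platt,
    threshold = signature$threshold,
    selected_k = signature$selected_k,
    train_loocv_auc = signature$train_auc
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
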