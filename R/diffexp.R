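#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits, for every gene, the two-group contrast case minus control on
#' `log2(TPM + 1)` values and moderates the gene-wise residual variances by
#' shrinking them toward a common prior. The prior is a scaled inverse
#' chi-square with `d0` degrees of freedom and scale `s0_sq`, estimated by
#' matching the first two moments of the log residual variances to the
#' log-F distribution they follow under the model (the trigamma moment
#' equations, solved by Newton inversion). The moderated statistic is
#' \deqn{\tilde t_g = \frac{\bar y_{g,case} - \bar y_{g,control}}
#'   {\tilde s_g \sqrt{1/n_1 + 1/n_2}},\qquad
#'   \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' referred to a t distribution on \eqn{d_0 + d_g} degrees of freedom,
#' with Benjamini-Hochberg adjustment across genes.
#'
#' @param log_expr an [exlr_matrix()] with unit `"log2tpm"`.
#' @param labels logical or 0/1 vector over samples; `TRUE`/1 = case.
#' @param tpm optional matching TPM matrix used to annotate expression
#'   frequency (detection fraction) and group mean TPM per gene.
#' @param annotation optional annotation tibble used to attach biotypes.
#' @param d0_override force the prior degrees of freedom: `0` gives the
#'   ordinary pooled-variance t, `Inf` full shrinkage to `s0_sq`.
#' @return an object of class `exlr_de_fit`; use [tidy()] for the per-gene
#'   table and [glance()] for the prior estimates.
#' @export
fit_moderated_t <- function(log_expr, labels, tpm = NULL, annotation = NULL,
                            d0_override = NULL) {
  assert_unit(log_expr, "log2tpm")
  labels <- as_binary_labels(labels, ncol(log_expr))
  n1 <- sum(labels)          # case
  n2 <- sum(!labels)         # control
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples.")
  x <- unclass(log_expr)
  case <- x[, labels, drop = FALSE]
  ctrl <- x[, !labels, drop = FALSE]
  mean_case <- rowMeans(case)
  mean_ctrl <- rowMeans(ctrl)
  log2fc <- mean_case - mean_ctrl
  # pooled residual variance, d_g = n - 2
  ss <- rowSums((case - mean_case)^2) + rowSums((ctrl - mean_ctrl)^2)
  dg <- n1 + n2 - 2
  s2 <- ss / dg
  n_floored <- sum(s2 < .Machine$double.eps)
  if (n_floored > 0) {
    warn(sprintf("%d zero-variance gene(s); variance floored at machine eps.",
                 n_floored))
    s2 <- pmax(s2, .Machine$double.eps)
  }
  if (is.null(d0_override)) {
    prior <- estimate_variance_prior(s2, dg)
  } else {
    if (d0_override < 0) abort("d0_override must be >= 0.")
    s0 <- if (is.infinite(d0_override)) exp(mean(log(s2))) else mean(s2)
    prior <- list(d0 = d0_override, s0_sq = s0)
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else {
    if (d0 == 0) s2 else (d0 * s0_sq + dg * s2) / (d0 + dg)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- log2fc / se
  df_total <- d0 + dg
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- tibble(
    gene_id = rownames(x),
    log2fc = unname(log2fc),
    t_mod = unname(t_mod),
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    s2 = unname(s2),
    s2_post = unname(s2_post)
  )
  if (!is.null(tpm)) {
    assert_unit(tpm, "tpm")
    if (!all(colnames(x) %in% colnames(tpm))) {
      abort("`tpm` must cover every sample in `log_expr`.")
    }
    tt <- unclass(tpm)[res$gene_id, colnames(x), drop = FALSE]
    res$mean_case_tpm <- rowMeans(tt[, labels, drop = FALSE])
    res$mean_control_tpm <- rowMeans(tt[, !labels, drop = FALSE])
    res$expression_frequency <- rowMeans(tt > 0)
  }
  if (!is.null(annotation)) {
    res$biotype <- annotation$biotype[match(res$gene_id, annotation$gene_id)]
  }
  structure(
    list(table = res, d0 = d0, s0_sq = s0_sq, df_residual = dg,
         n_case = n1, n_control = n2),
    class = "exlr_de_fit"
  )
}

as_binary_labels <- function(labels, n) {
  if (length(labels) != n) abort("labels length must match sample count.")
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  abort("labels must be logical or 0/1.")
}

# Moment estimation of the scaled inverse chi-square variance prior.
# Under the hierarchical model, z_g = log s_g^2 satisfies
#   E[z] = log s0^2 + digamma(d0/2) - log(d0/2)
#        - (digamma(dg/2) - log(dg/2))
#   Var[z] = trigamma(dg/2) + trigamma(d0/2)
# so trigamma(d0/2) is the excess variance of z over its sampling component;
# no positive excess means no evidence of variance heterogeneity -> d0 = Inf.
estimate_variance_prior <- function(s2, dg) {
  z <- log(s2)
  e <- z - digamma(dg / 2) + log(dg / 2)
  n <- length(z)
  excess <- mean((e - mean(e))^2) * n / (n - 1) - trigamma(dg / 2)
  if (!is.finite(excess) || excess <= 0) {
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function on (0, Inf).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' @export
print.exlr_de_fit <- function(x, ...) {
  cat(sprintf(
    "<exlr_de_fit> %d genes, %d case vs %d control; d0 = %.3g, s0^2 = %.3g\n",
    nrow(x$table), x$n_case, x$n_control, x$d0, x$s0_sq))
  invisible(x)
}

#' @rdname fit_moderated_t
#' @param x,object an `exlr_de_fit`.
#' @param ... unused.
#' @method tidy exlr_de_fit
#' @export
tidy.exlr_de_fit <- function(x, ...) x$table

#' @rdname fit_moderated_t
#' @method glance exlr_de_fit
#' @export
glance.exlr_de_fit <- function(x, ...) {
  tibble(d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$df_residual,
         n_case = x$n_case, n_control = x$n_control,
         n_genes = nrow(x$table))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` with input checking.
#'
#' @param p vector of p-values in `[0, 1]`, no NAs.
#' @return adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) abort("NA p-values are not allowed.")
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Expression frequency (detection fraction) of a gene
#'
#' Fraction of the given samples in which the gene's TPM exceeds the
#' detection threshold (default 0, i.e. any nonzero expression counts as
#' detected).
#'
#' @param tpm an [exlr_matrix()] with unit `"tpm"`.
#' @param gene a gene ID present in `tpm`.
#' @param samples sample IDs to consider (default all).
#' @param threshold TPM detection cutoff (strict inequality).
#' @return a number in `[0, 1]`.
#' @export
expression_frequency <- function(tpm, gene, samples = colnames(tpm),
                                 threshold = 0) {
  assert_unit(tpm, "tpm")
  if (!gene %in% rownames(tpm)) abort(sprintf("unknown gene '%s'.", gene))
  if (!length(samples)) abort("empty sample subset.")
  missing <- setdiff(samples, colnames(tpm))
  if (length(missing)) abort(paste0("unknown sample(s): ",
                                    paste(missing, collapse = ", ")))
  mean(unclass(tpm)[gene, samples] > threshold)
}

#' Filter differential-expression results to signature candidates
#'
#' Keeps upregulated long-RNA genes passing the screening rules used to
#' nominate candidate marker genes: biotype protein-coding or lncRNA,
#' `log2fc` above `log2fc_min` (default 0.59, i.e. fold change around 1.5),
#' BH-adjusted p below `adj_p_max`, and expression frequency above
#' `freq_min`. The result is ordered by descending log2 fold change with
#' gene ID as the deterministic tiebreak.
#'
#' @param de tidy DE table from [fit_moderated_t()] (via [tidy()]) with
#'   columns `gene_id`, `log2fc`, `adj_p`, `expression_frequency`, `biotype`.
#' @param log2fc_min,adj_p_max,freq_min candidate thresholds.
#' @param biotypes biotypes eligible as candidates.
#' @return character vector of candidate gene IDs, in rank order.
#' @export
select_candidates <- function(de, log2fc_min = 0.59, adj_p_max = 0.05,
                              freq_min = 0.5,
                              biotypes = c("protein_coding", "lncRNA")) {
  if (inherits(de, "exlr_de_fit")) de <- tidy(de)
  needed <- c("gene_id", "log2fc", "adj_p", "expression_frequency", "biotype")
  missing <- setdiff(needed, names(de))
  if (length(missing)) {
    abort(paste0("DE table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  hits <- de |>
    dplyr::filter(
      .data$biotype %in% biotypes,
      .data$log2fc > log2fc_min,
      .data$adj_p < adj_p_max,
      .data$expression_frequency > freq_min
    ) |>
    dplyr::arrange(dplyr::desc(.data$log2fc), .data$gene_id)
  if (nrow(hits) == 0) abort("no candidate genes pass the rules; relax them.")
  hits$gene_id
}
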