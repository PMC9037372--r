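#' Convert read counts to TPM over long-RNA genes
#'
#' Transcripts per million for gene *i* in a sample is
#' \deqn{TPM_i = \frac{RC_i / L_i}{\sum_j RC_j / L_j} \times 10^6,}
#' where \eqn{RC_i} is the read count, \eqn{L_i} the gene length in base
#' pairs, and the denominator runs over the long-RNA genes retained —
#' by default protein-coding and lncRNA genes only, so TPM is relative
#' abundance within the long-RNA fraction of the library.
#'
#' @param counts an [exlr_matrix()] with unit `"counts"`.
#' @param annotation annotation tibble with `gene_id`, `biotype`,
#'   `length_bp` covering every gene in `counts`.
#' @param biotypes biotypes kept before normalization.
#' @return an [exlr_matrix()] with unit `"tpm"`; every column sums to 1e6.
#' @examples
#' counts <- exlr_matrix(matrix(c(100L, 100L), 2, 1,
#'   dimnames = list(c("a", "b"), "s1")), unit = "counts")
#' ann <- tibble::tibble(gene_id = c("a", "b"), symbol = c("A", "B"),
#'   biotype = "protein_coding", length_bp = c(1000L, 2000L))
#' compute_tpm(counts, ann)
#' @export
compute_tpm <- function(counts, annotation,
                        biotypes = c("protein_coding", "lncRNA")) {
  assert_unit(counts, "counts")
  missing <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing)) {
    abort(paste0("genes missing from annotation: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  keep <- ann$biotype %in% biotypes
  if (!any(keep)) abort("no genes left after biotype restriction.")
  rc <- unclass(counts)[keep, , drop = FALSE]
  len <- ann$length_bp[keep]
  rate <- rc / len
  totals <- colSums(rate)
  if (any(totals == 0)) {
    abort(sprintf("sample '%s' has zero total read rate.",
                  colnames(rc)[which(totals == 0)[1]]))
  }
  exlr_matrix(sweep(rate, 2, totals, "/") * 1e6, unit = "tpm")
}

#' Sample quality control by median inter-sample correlation
#'
#' For each sample, computes the median of its correlation coefficients with
#' every other sample and removes samples whose median falls below
#' `threshold` (default 0.9). Correlations are Pearson on `log2(TPM + 1)` by
#' default; `method = "spearman"` and `log = FALSE` (correlate raw TPM) are
#' available since the appropriate scale is a judgment call.
#'
#' @param tpm an [exlr_matrix()] with unit `"tpm"`; at least 3 samples.
#' @param threshold minimum median correlation for a sample to be kept.
#' @param method correlation type.
#' @param log correlate log2(TPM + 1) rather than raw TPM.
#' @return a list with `matrix` (the filtered TPM matrix) and `report`, a
#'   tibble with `sample_id`, `median_correlation`, `kept`, `threshold`.
#' @export
sample_qc <- function(tpm, threshold = 0.9,
                      method = c("pearson", "spearman"), log = TRUE) {
  assert_unit(tpm, "tpm")
  method <- match.arg(method)
  if (ncol(tpm) < 3) abort("sample_qc needs at least 3 samples.")
  x <- if (log) log2(unclass(tpm) + 1) else unclass(tpm)
  cc <- cor(x, method = method)
  diag(cc) <- NA
  med <- apply(cc, 2, median, na.rm = TRUE)
  kept <- med >= threshold
  if (!any(kept)) abort("sample_qc would remove every sample.")
  report <- tibble(
    sample_id = colnames(tpm),
    median_correlation = unname(med),
    kept = unname(kept),
    threshold = threshold
  )
  list(matrix = tpm[, kept, drop = FALSE] |> exlr_matrix(unit = "tpm"),
       report = report)
}
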