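#' Expression matrix with a tracked unit
#'
#' An `exlr_matrix` is a plain numeric genes x samples matrix carrying a
#' `unit` attribute, one of `"counts"`, `"tpm"` or `"log2tpm"`. The unit is
#' validated at construction: counts must be non-negative integers, and every
#' column of a TPM matrix must sum to one million (relative tolerance 1e-9).
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs).
#' @param unit expression unit of `values`.
#' @return `values` with class `exlr_matrix` and the `unit` attribute set.
#' @examples
#' m <- exlr_matrix(matrix(c(50, 0, 10, 40), 2, 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), unit = "counts")
#' expr_unit(m)
#' @export
exlr_matrix <- function(values, unit = c("counts", "tpm", "log2tpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    abort(paste0("duplicate gene_id: ",
                 paste(unique(rownames(values)[duplicated(rownames(values))]),
                       collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    abort("duplicate sample_id in matrix columns.")
  }
  if (anyNA(values)) abort("expression matrix contains NA values.")
  if (unit != "log2tpm" && any(values < 0)) {
    abort(sprintf("%s matrix must be non-negative.", unit))
  }
  if (unit == "counts" && any(values != round(values))) {
    bad <- which(values != round(values), arr.ind = TRUE)[1, ]
    abort(sprintf("non-integer count at gene '%s', sample '%s'.",
                  rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (unit == "tpm") {
    cs <- colSums(values)
    rel <- abs(cs - 1e6) / 1e6
    if (any(rel > 1e-9)) {
      abort(sprintf("TPM column '%s' sums to %.6f, not 1e6.",
                    colnames(values)[which.max(rel)], cs[which.max(rel)]))
    }
  }
  structure(values, unit = unit, class = c("exlr_matrix", class(values)))
}

#' @rdname exlr_matrix
#' @param x an `exlr_matrix`.
#' @export
expr_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) abort("matrix has no unit attribute; use exlr_matrix().")
  u
}

#' @export
print.exlr_matrix <- function(x, ...) {
  cat(sprintf("<exlr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  print(head(unclass(x)[, seq_len(min(5L, ncol(x))), drop = FALSE], 5L))
  invisible(x)
}

# subsetting keeps the class and unit (a sliced TPM matrix no longer sums to
# 1e6, so slices of tpm matrices are returned as bare matrices)
#' @export
`[.exlr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out) && expr_unit(x) != "tpm") {
    structure(out, unit = expr_unit(x), class = class(x))
  } else {
    out
  }
}

assert_unit <- function(x, unit) {
  if (!inherits(x, "exlr_matrix") || expr_unit(x) != unit) {
    abort(sprintf("expected an exlr_matrix with unit '%s'.", unit))
  }
  invisible(x)
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(TPM + pseudocount)`, the transform used for QC correlations,
#' differential expression and classification throughout the pipeline.
#'
#' @param tpm an `exlr_matrix` with unit `"tpm"`.
#' @param pseudocount value added before taking logs; default 1 keeps zeros at
#'   zero.
#' @return an `exlr_matrix` with unit `"log2tpm"`.
#' @export
log2_tpm <- function(tpm, pseudocount = 1) {
  assert_unit(tpm, "tpm")
  exlr_matrix(log2(unclass(tpm) + pseudocount), unit = "log2tpm")
}

#' Convert an expression matrix to a tidy tibble
#'
#' @param x an `exlr_matrix`.
#' @param ... unused.
#' @return a tibble with columns `gene_id`, `sample_id`, `value`, `unit`.
#' @method tidy exlr_matrix
#' @export
tidy.exlr_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x)),
    unit = expr_unit(x)
  )
}
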