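#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (midranks for ties) and
#' each gene set scored by walking down the sample's ranking, accumulating
#' the difference between a rank-weighted in-set empirical CDF (weights
#' \eqn{r^\alpha}, *r* the gene's within-sample rank, largest for the most
#' expressed gene) and the uniform CDF over out-of-set genes; the score is
#' the sum of that difference over all positions. Being purely rank-based,
#' scores are invariant to any strictly increasing within-sample transform,
#' so TPM and log2-TPM inputs give identical results.
#'
#' @param expr an [exlr_matrix()], unit `"tpm"` or `"log2tpm"`.
#' @param sets named list of gene-ID vectors ([read_gmt()]).
#' @param alpha rank-weight exponent.
#' @param normalize `"raw"` scores, or `"range"`: divide the whole matrix by
#'   its score range so values lie within [-1, 1].
#' @param strict error (rather than warn and skip) on sets with no member
#'   in the matrix.
#' @return sets x samples numeric matrix of enrichment scores with
#'   attribute `normalization`.
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25,
                         normalize = c("raw", "range"), strict = FALSE) {
  normalize <- match.arg(normalize)
  if (!inherits(expr, "exlr_matrix") ||
      !expr_unit(expr) %in% c("tpm", "log2tpm")) {
    abort("expected an exlr_matrix with unit 'tpm' or 'log2tpm'.")
  }
  x <- unclass(expr)
  genes <- rownames(x)
  n <- nrow(x)
  present <- purrr::map(sets, ~ intersect(unique(.x), genes))
  empty <- names(sets)[lengths(present) == 0]
  if (length(empty)) {
    msg <- paste0("gene set(s) with no member in the matrix: ",
                  paste(empty, collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, " — skipped."))
    present <- present[lengths(present) > 0]
  }
  if (!length(present)) abort("no scorable gene sets.")
  member <- purrr::map(present, ~ genes %in% .x)
  out <- matrix(NA_real_, length(present), ncol(x),
                dimnames = list(names(present), colnames(x)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    # deterministic walk: decreasing expression, gene id breaks exact ties
    ord <- order(-x[, j], genes)
    w <- r[ord]^alpha
    for (s in seq_along(member)) {
      inset <- member[[s]][ord]
      n_out <- max(n - sum(inset), 1L)  # set == all genes: no out-of-set term
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / n_out
      out[s, j] <- sum(p_in - p_out)
    }
  }
  if (normalize == "range") {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  attr(out, "normalization") <- normalize
  out
}

#' Hypergeometric over-representation analysis
#'
#' Tests each pathway for enrichment of a differentially-expressed gene list
#' within a gene universe: p is the upper-tail hypergeometric probability of
#' observing at least the realized overlap, BH-adjusted across pathways.
#' Pathways are intersected with the universe first.
#'
#' @param deg character vector of DE gene IDs (subset of `universe`).
#' @param universe character vector of all tested gene IDs.
#' @param pathways named list of gene-ID vectors.
#' @return tibble with `pathway`, `size` (in-universe pathway size),
#'   `overlap`, `p`, `adj_p`, ordered by p.
#' @export
ora_hypergeometric <- function(deg, universe, pathways) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe.")
  deg <- unique(deg)
  stray <- setdiff(deg, universe)
  if (length(stray)) {
    abort(paste0("DEG(s) outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  n_univ <- length(universe)
  n_deg <- length(deg)
  rows <- purrr::imap(pathways, function(members, nm) {
    inside <- intersect(unique(members), universe)
    k <- length(intersect(inside, deg))
    p <- phyper(k - 1, length(inside), n_univ - length(inside), n_deg,
                lower.tail = FALSE)
    tibble(pathway = nm, size = length(inside), overlap = k, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- bh_adjust(out$p)
  dplyr::arrange(out, .data$p, .data$pathway)
}

#' Compare enrichment scores between the three cohorts
#'
#' Per gene set: Wilcoxon rank-sum p for each cohort pair (exact when both
#' groups have <= `exact_max` samples, normal approximation with tie
#' correction otherwise), one-way ANOVA p across the three cohorts, and a
#' monotone-trend flag set when group medians are strictly ordered
#' CRC < CRA < healthy or the reverse.
#'
#' @param scores sets x samples matrix from [ssgsea_score()].
#' @param design design tibble with `sample_id`, `cohort`.
#' @param exact_max maximum per-group size for exact Wilcoxon p-values.
#' @return tibble with one row per set: `set`, `p_crc_cra`, `p_crc_healthy`,
#'   `p_cra_healthy`, `p_anova`, `trend`, `direction`.
#' @export
group_compare <- function(scores, design, exact_max = 10) {
  design <- validate_design(design)
  common <- intersect(colnames(scores), design$sample_id)
  if (!length(common)) abort("no samples in common.")
  scores <- scores[, common, drop = FALSE]
  cohort <- design$cohort[match(common, design$sample_id)]
  groups <- c("CRC", "CRA", "healthy")
  pairs <- list(c("CRC", "CRA"), c("CRC", "healthy"), c("CRA", "healthy"))
  rows <- purrr::map(rownames(scores), function(set) {
    v <- scores[set, ]
    pw <- vapply(pairs, function(pr) {
      a <- v[cohort == pr[1]]; b <- v[cohort == pr[2]]
      if (length(a) < 2 || length(b) < 2) return(NA_real_)
      exact <- length(a) <= exact_max && length(b) <= exact_max
      suppressWarnings(
        wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
    }, numeric(1))
    have <- groups[groups %in% cohort]
    p_anova <- if (length(have) == 3 &&
                   all(table(cohort)[groups] >= 2) && sd(v) > 0) {
      oneway.test(v ~ factor(cohort, levels = groups),
                  var.equal = TRUE)$p.value
    } else NA_real_
    med <- vapply(groups, function(g) {
      if (any(cohort == g)) median(v[cohort == g]) else NA_real_
    }, numeric(1))
    trend <- !anyNA(med) &&
      (all(diff(med) > 0) || all(diff(med) < 0))
    tibble(set = set,
           p_crc_cra = pw[1], p_crc_healthy = pw[2], p_cra_healthy = pw[3],
           p_anova = p_anova, trend = trend,
           direction = if (anyNA(med)) NA_character_ else {
             if (med["CRC"] >= med["healthy"]) "decreasing" else "increasing"
           })
  })
  dplyr::bind_rows(rows)
}
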