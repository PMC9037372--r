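# shared fixture builders; everything is generated in code

make_matrix <- function(values, unit, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  exlr_matrix(values, unit = unit)
}

make_annotation <- function(gene_ids, lengths = NULL, biotypes = NULL) {
  n <- length(gene_ids)
  tibble::tibble(
    gene_id = gene_ids,
    symbol = toupper(gene_ids),
    biotype = if (is.null(biotypes)) rep("protein_coding", n) else biotypes,
    length_bp = if (is.null(lengths)) rep(1000L, n) else as.integer(lengths)
  )
}

# small gaussian log-expression matrix with optional informative genes
make_log_expr <- function(n_genes, n_case, n_control, n_info = 0,
                          effect = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- n_case + n_control
    x <- matrix(rnorm(n_genes * n, 5, 1), n_genes, n)
    if (n_info > 0) {
      x[seq_len(n_info), seq_len(n_case)] <-
        x[seq_len(n_info), seq_len(n_case)] + effect
    }
    dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                        sprintf("s%03d", seq_len(n)))
    list(expr = exlr_matrix(x, unit = "log2tpm"),
         labels = rep(c(TRUE, FALSE), c(n_case, n_control)))
  })
}

small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 400, n_crc = 18, n_cra = 10, n_healthy = 20,
                   n_planted_up = 8, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# brute-force BH step-up, straight from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    candidates <- vapply(seq(rank_i, m), function(j) p[o[j]] * m / j,
                         numeric(1))
    adj[i] <- min(1, min(candidates))
  }
  adj
}

# brute-force AUC by enumerating case/control pairs with half tie credit
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# brute-force greedy MIQ ranking with explicit double loops
mrmr_brute <- function(disc, labels, candidates, eps = 1e-12) {
  candidates <- sort(unique(candidates))
  rel <- sapply(candidates, function(g) mutual_information(disc[g, ], labels))
  selected <- character(0)
  while (length(selected) < length(candidates)) {
    remaining <- setdiff(candidates, selected)
    best <- NULL; best_score <- -Inf
    for (f in remaining) {
      if (length(selected) == 0) {
        score <- rel[[f]]
      } else {
        red <- mean(sapply(selected, function(s)
          mutual_information(disc[f, ], disc[s, ])))
        score <- rel[[f]] / max(red, eps)
      }
      if (score > best_score + 1e-12) { best <- f; best_score <- score }
    }
    selected <- c(selected, best)
  }
  selected
}
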