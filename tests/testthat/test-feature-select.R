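test_that("discretization codes values against mu +/- alpha*sigma", {
  x <- matrix(c(-10, 0, 10, 3, 3, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("var", "const"), c("a", "b", "c")))
  d <- discretize_expression(exlr_matrix(x, unit = "log2tpm"), alpha = 1)
  expect_equal(unname(d["var", ]), c(-1L, 0L, 1L))
  expect_equal(unname(d["const", ]), c(0L, 0L, 0L))
  # alpha -> infinity: everything in the neutral band
  d2 <- discretize_expression(exlr_matrix(x, unit = "log2tpm"), alpha = 1e6)
  expect_true(all(d2 == 0L))
})

test_that("mutual information matches hand-computed plug-in values", {
  # independent 2x2 product table
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  # identical balanced binary vectors: 1 bit
  expect_equal(mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  # joint counts ((3,1),(1,3))
  x <- rep(c(0, 0, 1, 1), c(3, 1, 1, 3))
  y <- rep(c(0, 1, 0, 1), c(3, 1, 1, 3))
  expected <- 2 * (3 / 8) * log2(3 / 2) + 2 * (1 / 8) * log2(1 / 2)
  expect_equal(mutual_information(x, y), expected, tolerance = 1e-12)
  expect_equal(mutual_information(x, y), mutual_information(y, x))
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("MI is non-negative and zero iff the sample joint factorizes", {
  withr::with_seed(21, {
    for (i in 1:25) {
      x <- sample(c(-1, 0, 1), 30, replace = TRUE)
      y <- sample(c(-1, 0, 1), 30, replace = TRUE)
      mi <- mutual_information(x, y)
      expect_gte(mi, -1e-12)
      joint <- table(x, y) / 30
      factorizes <- all(abs(joint - outer(rowSums(joint), colSums(joint)))
                        < 1e-12)
      expect_equal(mi < 1e-12, factorizes)
    }
  })
})

test_that("MIQ greedy ranking equals the brute-force oracle on toy instances", {
  withr::with_seed(33, {
    for (rep in 1:20) {
      n <- sample(20:60, 1)
      k <- sample(3:8, 1)
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      while (sum(labels) < 2 || sum(!labels) < 2) {
        labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      }
      disc <- matrix(sample(c(-1L, 0L, 1L), k * n, replace = TRUE), k, n,
                     dimnames = list(sprintf("g%02d", 1:k),
                                     sprintf("s%02d", 1:n)))
      # make a couple of features informative and one a duplicate
      disc[1, ] <- ifelse(labels, 1L, -1L)
      disc[1, sample(n, ceiling(n / 5))] <- 0L
      if (k >= 3) disc[3, ] <- disc[1, ]
      ranking <- mrmr_rank_miq(disc, labels)
      expect_equal(ranking$gene_id, mrmr_brute(disc, labels, rownames(disc)))
    }
  })
})

test_that("ranking is invariant to candidate order and demotes duplicates", {
  # deterministic instance: a_top and b_dup are identical noisy label copies,
  # c_alt is an independently-degraded label copy. The MIQ quotient must
  # prefer c_alt over the exact duplicate at step 2.
  n <- 40
  labels <- rep(c(TRUE, FALSE), each = 20)
  a_top <- ifelse(labels, 1L, -1L)
  a_top[c(1:4, 21:24)] <- 0L
  c_alt <- ifelse(labels, 1L, -1L)
  c_alt[c(9:14, 29:34)] <- 0L
  disc <- rbind(a_top = a_top, b_dup = a_top, c_alt = c_alt)
  colnames(disc) <- sprintf("s%02d", 1:n)
  r1 <- mrmr_rank_miq(disc, labels, rownames(disc))
  r2 <- mrmr_rank_miq(disc, labels, rev(rownames(disc)))
  expect_equal(r1, r2)
  expect_equal(r1$gene_id[1], "a_top")  # relevance tie broken by ID
  expect_equal(r1$gene_id[2], "c_alt")  # duplicate demoted by redundancy
  expect_equal(r1$gene_id, mrmr_brute(disc, labels, rownames(disc)))
})

test_that("single-candidate ranking carries its relevance as score", {
  labels <- rep(c(TRUE, FALSE), each = 5)
  disc <- matrix(ifelse(labels, 1L, -1L), 1, 10,
                 dimnames = list("solo", sprintf("s%02d", 1:10)))
  r <- mrmr_rank_miq(disc, labels)
  expect_equal(nrow(r), 1L)
  expect_equal(r$score, r$relevance)
  expect_equal(r$relevance, mutual_information(disc[1, ], labels))
})

test_that("rank-statistic AUC equals pairwise enumeration with tie credit", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 1.0)
  withr::with_seed(12, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
      labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(labels) || all(labels)) next
      expect_identical(roc_auc(scores, labels), auc_brute(scores, labels))
    }
  })
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC matches pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(13, {
    for (i in 1:10) {
      scores <- rnorm(40)
      labels <- rbinom(40, 1, 0.5)
      if (sum(labels) %in% c(0, 40)) next
      ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                            direction = "<",
                                            levels = c(0, 1), quiet = TRUE)))
      expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
    }
  })
})

test_that("LOOCV scores equal independent per-fold train/predict runs", {
  f <- make_log_expr(12, 8, 10, n_info = 3, effect = 1.5, seed = 22)
  feats <- rownames(f$expr)[1:5]
  params <- default_svm_params()
  got <- loocv_scores(f$expr, f$labels, feats, params)
  x <- t(unclass(f$expr)[feats, ])
  for (i in seq_len(nrow(x))) {
    xtr <- x[-i, , drop = FALSE]
    ctr <- colMeans(xtr)
    sca <- apply(xtr, 2, sd)
    sca[sca == 0] <- 1
    xs <- sweep(sweep(xtr, 2, ctr, "-"), 2, sca, "/")
    yf <- factor(ifelse(f$labels[-i], "case", "control"),
                 levels = c("control", "case"))
    w <- length(yf) / (2 * table(yf))
    m <- e1071::svm(x = xs, y = yf, kernel = "linear", cost = 1,
                    scale = FALSE,
                    class.weights = setNames(as.numeric(w), names(w)))
    newx <- sweep(sweep(x[i, , drop = FALSE], 2, ctr, "-"), 2, sca, "/")
    pr <- predict(m, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    ref <- as.numeric(dv[, 1]) * (if (colnames(dv)[1] == "case/control") 1 else -1)
    expect_identical(unname(got[i]), ref)
  }
})

test_that("LOOCV separates well-separated clouds and ignores constant features", {
  f <- make_log_expr(3, 10, 10, n_info = 1, effect = 5, seed = 23)
  sc <- loocv_scores(f$expr, f$labels, rownames(f$expr)[1])
  expect_true(all(sc[f$labels] > 0) && all(sc[!f$labels] < 0))

  x <- unclass(f$expr)
  x["g002", ] <- 7  # constant gene
  m2 <- exlr_matrix(x, unit = "log2tpm")
  sc_pair <- loocv_scores(m2, f$labels, c("g001", "g002"))
  sc_solo <- loocv_scores(m2, f$labels, "g001")
  expect_equal(sc_pair, sc_solo, tolerance = 1e-9)
})

test_that("LOOCV AUC under permuted labels hovers at 0.5", {
  f <- make_log_expr(5, 10, 10, n_info = 0, seed = 24)
  aucs <- withr::with_seed(25, {
    vapply(1:20, function(r) {
      lab <- sample(f$labels)
      roc_auc(loocv_scores(f$expr, lab, rownames(f$expr)), lab)
    }, numeric(1))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("IFS picks the smallest k at the AUC maximum and recovers planted genes", {
  # smallest-argmax convention on a synthetic curve via a direct call
  fake_ranking <- tibble::tibble(gene_id = c("a", "b", "c", "d"))
  # construct data where features a+b separate perfectly, c/d are noise
  withr::with_seed(26, {
    n <- 30
    labels <- rep(c(TRUE, FALSE), c(12, 18))
    x <- rbind(
      a = ifelse(labels, 2, -2) + rnorm(n, 0, 0.4),
      b = ifelse(labels, 1.5, -1.5) + rnorm(n, 0, 0.4),
      c = rnorm(n),
      d = rnorm(n)
    )
    colnames(x) <- sprintf("s%02d", 1:n)
  })
  sig <- ifs_select(fake_ranking, exlr_matrix(x, unit = "log2tpm"), labels)
  expect_equal(sig$ifs_curve$loocv_auc,
               vapply(1:4, function(k) {
                 roc_auc(loocv_scores(exlr_matrix(x, unit = "log2tpm"),
                                      labels, fake_ranking$gene_id[1:k]),
                         labels)
               }, numeric(1)))
  expect_equal(sig$selected_k,
               which.max(sig$ifs_curve$loocv_auc))
  expect_true(all(sig$features %in% c("a", "b", "c", "d")))
  expect_equal(sig$features, fake_ranking$gene_id[seq_len(sig$selected_k)])
})

test_that("end-to-end selection recovers planted informative genes", {
  withr::with_seed(27, {
    n <- 60
    labels <- rep(c(TRUE, FALSE), each = 30)
    planted <- sprintf("info%d", 1:3)
    x <- matrix(rnorm(30 * n, 5, 1), 30, n,
                dimnames = list(c(planted, sprintf("noise%02d", 1:27)),
                                sprintf("s%02d", 1:n)))
    x[planted, labels] <- x[planted, labels] + 1.8
  })
  expr <- exlr_matrix(x, unit = "log2tpm")
  disc <- discretize_expression(expr)
  ranking <- mrmr_rank_miq(disc, labels)
  sig <- ifs_select(ranking, expr, labels, k_max = 10)
  expect_gte(sum(planted %in% sig$features), 2)
  expect_true(all(sig$features == ranking$gene_id[seq_along(sig$features)]))
})
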