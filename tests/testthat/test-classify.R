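test_that("Platt calibration is monotone and anchored at the midpoint", {
  withr::with_seed(31, {
    scores <- c(rnorm(30, -1), rnorm(30, 1))
  })
  labels <- rep(c(FALSE, TRUE), each = 30)
  platt <- fit_platt(scores, labels)
  expect_gt(platt$b, 0)
  s_grid <- seq(-3, 3, length.out = 50)
  p <- 1 / (1 + exp(-(platt$a + platt$b * s_grid)))
  expect_true(all(diff(p) > 0))
  # probability 0.5 exactly at the sigmoid midpoint -a/b
  mid <- -platt$a / platt$b
  expect_equal(1 / (1 + exp(-(platt$a + platt$b * mid))), 0.5)

  # perfectly separated scores still give a finite, oriented sigmoid
  sep <- fit_platt(c(-2, -1, 1, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(is.finite(sep$a) && is.finite(sep$b) && sep$b > 0)
})

test_that("predictions use frozen statistics and probabilities track scores", {
  f <- make_log_expr(10, 10, 12, n_info = 3, effect = 2, seed = 32)
  ranking <- tibble::tibble(gene_id = rownames(f$expr)[1:5])
  sig <- ifs_select(ranking, f$expr, f$labels, k_max = 3)
  pred <- predict(sig, f$expr)
  expect_named(pred, c("sample_id", "score", "probability"))
  ord <- order(pred$score)
  expect_true(all(diff(pred$probability[ord]) >= 0))
  # a clear case-side training sample gets probability > 0.5
  expect_gt(max(pred$probability[f$labels]), 0.5)
  # missing features are a hard error
  expect_error(predict(sig, f$expr[setdiff(rownames(f$expr),
                                           sig$features[1]), ]),
               "missing model feature")
})

test_that("Youden threshold lands in the optimal gap with ties at the low end", {
  expect_equal(choose_threshold(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2.5)
  # separable scores: gap midpoint
  expect_equal(choose_threshold(c(-5, -4, 4, 5), c(0, 0, 1, 1)), 0)
  # all-equal scores: the value itself, J = 0
  expect_equal(choose_threshold(rep(2, 6), rep(c(0, 1), 3)), 2)
  # tie in J resolved to the lower threshold
  thr <- choose_threshold(c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1))
  j <- function(t, s, l) mean(s[l == 1] > t) + mean(s[l == 0] <= t) - 1
  cand <- c(1.5, 2.5, 3.5, 4.5, 5.5)
  best <- max(vapply(cand, j, numeric(1), s = c(1, 2, 3, 4, 5, 6),
                     l = c(0, 0, 1, 0, 1, 1)))
  expect_equal(j(thr, c(1, 2, 3, 4, 5, 6), c(0, 0, 1, 0, 1, 1)), best)
  expect_equal(thr, min(cand[vapply(cand, j, numeric(1),
                                    s = c(1, 2, 3, 4, 5, 6),
                                    l = c(0, 0, 1, 0, 1, 1)) == best]))
  expect_equal(choose_threshold(1:4, c(0, 0, 1, 1), method = "fixed",
                                fixed = 9), 9)
})

test_that("evaluation metrics match direct confusion-table counts", {
  # TP=9 FN=1 TN=8 FP=2 at threshold 0
  scores <- c(rep(1, 9), -1, rep(-1, 8), rep(1, 2))
  labels <- rep(c(TRUE, FALSE), c(10, 10))
  ev <- evaluate_classifier(scores, labels, 0)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$specificity, 0.8)
  expect_equal(ev$accuracy, 0.85)
  expect_equal(ev$n_case, 10)
  expect_equal(ev$n_control, 10)

  perfect <- evaluate_classifier(c(1, 2, 9, 10), c(0, 0, 1, 1), 5)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)
  expect_lte(perfect$ci_high, 1)
})

test_that("evaluation respects label-flip symmetry", {
  withr::with_seed(33, {
    scores <- rnorm(60)  # continuous: no score equals the threshold
  })
  labels <- rep(c(TRUE, FALSE), 30)
  a <- evaluate_classifier(scores, labels, 0.2)
  b <- evaluate_classifier(-scores, !labels, -0.2)
  expect_equal(b$auc, a$auc, tolerance = 1e-12)
  expect_equal(b$sensitivity, a$specificity, tolerance = 1e-12)
  expect_equal(b$specificity, a$sensitivity, tolerance = 1e-12)
  expect_equal(b$accuracy, a$accuracy, tolerance = 1e-12)
})

test_that("DeLong CI matches pROC and approximates the bootstrap CI", {
  skip_if_not_installed("pROC")
  withr::with_seed(34, {
    scores <- c(rnorm(60, 0), rnorm(60, 1))
  })
  labels <- rep(c(0, 1), each = 60)
  ev_d <- evaluate_classifier(scores, labels == 1, 0)
  r <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                 quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(r, method = "delong"))
  expect_equal(ev_d$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(ev_d$ci_high, ci[3], tolerance = 1e-6)

  ev_b <- evaluate_classifier(scores, labels == 1, 0,
                              ci_method = "bootstrap", boot_reps = 800,
                              boot_seed = 5L)
  expect_lt(abs((ev_d$ci_high - ev_d$ci_low) - (ev_b$ci_high - ev_b$ci_low)),
            0.06)
})

test_that("subgroup evaluation uses the frozen model and disjoint filters", {
  f <- make_log_expr(12, 14, 16, n_info = 4, effect = 2, seed = 35)
  design <- tibble::tibble(
    sample_id = colnames(f$expr),
    cohort = ifelse(f$labels, "CRC", rep(c("CRA", "healthy"), 8)),
    stage = ifelse(f$labels, rep(c("I", "II", "III", "IV"), length.out = 14),
                   NA_character_)
  )
  ranking <- tibble::tibble(gene_id = rownames(f$expr)[1:4])
  sig <- ifs_select(ranking, f$expr, f$labels, k_max = 2)
  plan <- list(
    subgroup("early CRC vs healthy",
             cohort == "CRC" & stage %in% c("I", "II"),
             cohort == "healthy"),
    subgroup("empty", cohort == "CRC" & stage == "X", cohort == "healthy")
  )
  expect_warning(rep_tbl <- evaluate_subgroups(sig, f$expr, design, plan),
                 "skipped")
  expect_equal(nrow(rep_tbl), 1L)
  expect_equal(rep_tbl$cohort_name, "early CRC vs healthy")
  expect_equal(rep_tbl$threshold, sig$threshold)
  expect_equal(rep_tbl$n_control, 8L)

  overlap <- list(subgroup("bad", cohort == "CRC", cohort == "CRC"))
  expect_error(evaluate_subgroups(sig, f$expr, design, overlap), "overlap")
})

test_that("evaluation-only steps are invariant to label shuffling (no refits)", {
  f <- make_log_expr(10, 12, 12, n_info = 3, effect = 2, seed = 36)
  ranking <- tibble::tibble(gene_id = rownames(f$expr)[1:4])
  sig <- ifs_select(ranking, f$expr, f$labels, k_max = 3)
  p1 <- predict(sig, f$expr)
  shuffled <- withr::with_seed(99, sample(f$labels))
  p2 <- predict(sig, f$expr)  # labels play no role in prediction
  expect_identical(p1, p2)
  ev1 <- evaluate_classifier(p1$score, f$labels, sig$threshold)
  ev2 <- evaluate_classifier(p2$score, f$labels, sig$threshold)
  expect_identical(ev1, ev2)
  # the shuffled labels change only the metrics, never the scores/threshold
  ev_shuf <- evaluate_classifier(p2$score, shuffled, sig$threshold)
  expect_identical(ev_shuf$threshold, ev1$threshold)
})
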