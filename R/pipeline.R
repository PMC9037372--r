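#' Stratified train/validation split
#'
#' Assigns each sample to `"train"` or `"validation"`, stratified by cohort
#' so CRC/CRA/healthy proportions match across splits (the study design's
#' 2:1 random division). The assignment is a pure function of the seed and
#' the sorted sample list: sample order in `design` does not matter.
#'
#' @param design design tibble.
#' @param prop_train fraction assigned to training, per cohort.
#' @param seed integer seed.
#' @return `design` with a `split` column.
#' @export
split_cohort <- function(design, prop_train = 2 / 3, seed = 1L) {
  design <- validate_design(design)
  split <- setNames(rep("validation", nrow(design)), design$sample_id)
  withr::with_seed(seed, {
    for (coh in sort(unique(design$cohort))) {
      ids <- sort(design$sample_id[design$cohort == coh])
      n_train <- round(prop_train * length(ids))
      split[sample(ids, n_train)] <- "train"
    }
  })
  design$split <- unname(split[design$sample_id])
  design
}

#' Pipeline configuration
#'
#' Collects every stage's tunable parameters with their defaults; unknown
#' names are rejected so typos cannot silently fall back to defaults.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `exlr_run_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    biotypes = LONG_RNA_BIOTYPES,
    qc_threshold = 0.9,
    qc_method = "pearson",
    qc_log = TRUE,
    pseudocount = 1,
    prop_train = 2 / 3,
    log2fc_min = 0.59,
    adj_p_max = 0.05,
    freq_min = 0.5,
    alpha_discretize = 1.0,
    k_max = 30L,
    svm_kernel = "linear",
    svm_cost = 1,
    svm_class_weights = TRUE,
    ssgsea_alpha = 0.25,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown pipeline_config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "exlr_run_config")
}

#' Run the full diagnostic-signature pipeline
#'
#' Chains the analysis stages on a counts matrix: TPM quantification over
#' long-RNA biotypes, sample QC by median correlation, a seeded stratified
#' train/validation split, moderated-t differential expression on the
#' training samples (case cohort vs the others pooled), candidate filtering,
#' mRMR-MIQ ranking, incremental feature selection with LOOCV-AUC-scored
#' SVMs, and frozen-model evaluation on the training and validation splits.
#' All randomness flows from `config$seed`.
#'
#' @param counts an [exlr_matrix()] with unit `"counts"`.
#' @param annotation annotation tibble.
#' @param design design tibble (a `split` column, if present, is used as-is;
#'   otherwise a split is drawn).
#' @param config an [pipeline_config()] object.
#' @param case cohort treated as case (default CRC; set `"CRA"` and
#'   `control = "healthy"` for the adenoma-vs-healthy signature — same
#'   pipeline, different contrast).
#' @param control cohorts pooled as control.
#' @param subgroup_plan optional list of [subgroup()] entries evaluated with
#'   the frozen model.
#' @param out_dir optional directory; if given, artifacts (TPM, QC report,
#'   DE table, IFS curve, model JSON, evaluation reports, manifest) are
#'   written as TSV/JSON.
#' @return list of class `exlr_run`: `tpm`, `qc`, `design`, `de_fit`,
#'   `candidates`, `ranking`, `signature`, `reports`, `predictions`,
#'   `config`.
#' @export
run_exlr_pipeline <- function(counts, annotation, design,
                              config = pipeline_config(),
                              case = "CRC",
                              control = c("CRA", "healthy"),
                              subgroup_plan = NULL,
                              out_dir = NULL) {
  if (!inherits(config, "exlr_run_config")) {
    abort("config must come from pipeline_config().")
  }
  design <- validate_design(design)

  tpm_all <- compute_tpm(counts, annotation, biotypes = config$biotypes)
  qc <- sample_qc(tpm_all, threshold = config$qc_threshold,
                  method = config$qc_method, log = config$qc_log)
  tpm <- qc$matrix
  joined <- join_design(tpm, design)
  tpm <- joined$matrix
  design <- joined$design

  if (!"split" %in% names(design) || anyNA(design$split)) {
    design <- split_cohort(design, prop_train = config$prop_train,
                           seed = config$seed)
  }
  keep <- design$cohort %in% c(case, control)
  tpm_used <- tpm[, design$sample_id[keep], drop = FALSE] |>
    exlr_matrix(unit = "tpm")
  design_used <- design[keep, , drop = FALSE]
  log_expr <- log2_tpm(tpm_used, pseudocount = config$pseudocount)
  labels <- design_used$cohort %in% case
  is_train <- design_used$split == "train"
  if (sum(is_train & labels) < 2 || sum(is_train & !labels) < 2) {
    abort("training split needs >= 2 samples per class.")
  }

  train_ids <- design_used$sample_id[is_train]
  log_train <- log_expr[, train_ids, drop = FALSE]
  de_fit <- fit_moderated_t(log_train, labels[is_train],
                            tpm = tpm_used, annotation = annotation)
  candidates <- select_candidates(tidy(de_fit),
                                  log2fc_min = config$log2fc_min,
                                  adj_p_max = config$adj_p_max,
                                  freq_min = config$freq_min)
  disc <- discretize_expression(log_train, alpha = config$alpha_discretize)
  ranking <- mrmr_rank_miq(disc, labels[is_train], candidates)
  svm_params <- default_svm_params(kernel = config$svm_kernel,
                                   cost = config$svm_cost,
                                   class_weights = config$svm_class_weights)
  k_max <- min(config$k_max, nrow(ranking))
  signature <- ifs_select(ranking, log_train, labels[is_train],
                          k_max = k_max, svm_params = svm_params)

  predictions <- predict(signature, log_expr) |>
    dplyr::left_join(design_used, by = "sample_id")
  reports <- dplyr::bind_rows(purrr::map(
    c("train", "validation"), function(sp) {
      idx <- design_used$split == sp
      if (sum(idx & labels) == 0 || sum(idx & !labels) == 0) return(NULL)
      sc <- predictions$score[match(design_used$sample_id[idx],
                                    predictions$sample_id)]
      evaluate_classifier(sc, labels[idx], signature$threshold,
                          cohort_name = sp)
    }))
  if (!is.null(subgroup_plan)) {
    reports <- dplyr::bind_rows(
      reports,
      evaluate_subgroups(signature, log_expr, design_used, subgroup_plan))
  }

  run <- structure(
    list(tpm = tpm, qc = qc$report, design = design, de_fit = de_fit,
         candidates = candidates, ranking = ranking, signature = signature,
         reports = reports, predictions = predictions, config = config),
    class = "exlr_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.exlr_run <- function(x, ...) {
  cat(sprintf("<exlr_run> %d samples kept, %d candidates, %d-gene signature\n",
              ncol(x$tpm), length(x$candidates), length(x$signature$features)))
  print(x$reports[, c("cohort_name", "auc", "sensitivity", "specificity",
                      "accuracy")])
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv_out(run$tpm, p("tpm.tsv"))
  write_tsv_out(run$qc, p("qc_report.tsv"))
  write_tsv_out(run$design, p("design.tsv"))
  write_tsv_out(tidy(run$de_fit), p("de.tsv"))
  writeLines(run$candidates, p("candidates.txt"))
  write_tsv_out(run$ranking, p("mrmr_ranking.tsv"))
  write_tsv_out(run$signature$ifs_curve, p("ifs_curve.tsv"))
  write_signature_json(run$signature, p("model.json"))
  write_tsv_out(run$reports, p("reports.tsv"))
  write_tsv_out(run$predictions, p("predictions.tsv"))
  manifest <- list(
    seed = run$config$seed,
    package_version = as.character(utils::packageVersion("exlr")),
    n_samples = ncol(run$tpm),
    n_candidates = length(run$candidates),
    selected_k = run$signature$selected_k,
    config = unclass(run$config)
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}
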