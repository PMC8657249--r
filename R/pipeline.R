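# End-to-end orchestration: cohort (loaded or simulated) -> 60/40 split ->
# tuned learner bank -> ejection -> correlation-based removal -> stacked
# meta-classifier (with- and without-removal variants) -> test-set metric
# table -> ensemble importance report. Every stochastic step derives from one
# run seed, so a rerun with the same configuration is bit-identical.

#' Default pipeline configuration
#'
#' @param seed run seed.
#' @param train_frac training fraction of the 60/40 split.
#' @param stratify stratified split? (plain random is the protocol-faithful
#'   mode; stratified is the stable default at ~12% prevalence).
#' @param bank learner names for [default_learner_bank()].
#' @param tuning list with `m`, `k`, `repeats` for [tuning_config()].
#' @param removal_threshold correlation cutoff for [removal_config()].
#' @param threshold classification threshold for the confusion matrix.
#' @param synthetic optional list of [synthetic_config()] arguments (used
#'   when no `data` entry is given).
#' @param data optional list with `path` (cohort CSV) and `schema` (list with
#'   `feature_names`, `feature_kinds`, `outcome_name`).
#' @return a plain list understood by [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, train_frac = 0.6, stratify = TRUE,
                            bank = c("lgr", "lda", "gam", "rda", "nb",
                                     "cart", "knn"),
                            tuning = list(m = 30L, k = 10L, repeats = 3L),
                            removal_threshold = 0.75, threshold = 0.5,
                            synthetic = list(n = 5000L), data = NULL,
                            compute_importance = TRUE,
                            importance_n_perm = 2L,
                            importance_max_rows = 1500L) {
  list(seed = seed, train_frac = train_frac, stratify = stratify, bank = bank,
       tuning = tuning, removal_threshold = removal_threshold,
       threshold = threshold, synthetic = synthetic, data = data,
       compute_importance = compute_importance,
       importance_n_perm = importance_n_perm,
       importance_max_rows = importance_max_rows)
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- pipeline_config()
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  config
}

resolve_cohort <- function(config) {
  if (!is.null(config$data)) {
    sch <- config$data$schema
    schema <- feature_schema(sch$feature_names, sch$feature_kinds,
                             sch$outcome_name)
    list(cohort = load_cohort(config$data$path, schema), truth = NULL)
  } else {
    args <- config$synthetic %||% list()
    args$seed <- args$seed %||% child_seed(config$seed, 11L)
    gen <- do.call(synthetic_config, args)
    generate_cohort(gen)
  }
}

#' Run the full stacked-ensemble pipeline
#'
#' Executes split, bank tuning, invalid-learner ejection, correlation-based
#' removal, meta-classifier stacking (both with- and without-removal
#' variants from the same tuned bank, so the contrast shares all upstream
#' randomness), test-set evaluation of every base learner and both
#' ensembles, and the ensemble importance table.
#'
#' @param config a [pipeline_config()] list or a path to a JSON file with
#'   the same fields.
#' @param out_dir optional directory; when given, metrics CSV, removal trace
#'   JSON, importance CSV, split CSV, run log and an importance plot (PDF)
#'   are written there.
#' @return list with `metrics` (data.frame, one row per classifier),
#'   `ensemble_with`, `ensemble_without`, `importance`, `removal_trace`,
#'   `tuned`, `split`, `cohort`, `truth`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  config <- read_pipeline_config(config)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  note("seed: %d", config$seed)

  src <- resolve_cohort(config)
  cohort <- src$cohort
  note("cohort: n=%d, events=%d (%.2f%%)", cohort$n, sum(cohort$labels),
       100 * mean(cohort$labels))

  split <- split_cohort(cohort, config$train_frac,
                        seed = child_seed(config$seed, 1L),
                        stratify = isTRUE(config$stratify))
  note("split: train=%d test=%d (stratified=%s; upsampling applied inside CV folds only)",
       length(split$train_idx), length(split$test_idx), config$stratify)
  train <- cohort_subset(cohort, split$train_idx)
  test <- cohort_subset(cohort, split$test_idx)

  bank <- default_learner_bank(config$bank)
  tcfg <- tuning_config(m = config$tuning$m, k = config$tuning$k,
                        repeats = config$tuning$repeats,
                        seed = child_seed(config$seed, 2L))
  tb <- tune_bank(bank, train, tcfg)
  for (nm in names(tb$tuned)) {
    note("tuned %s: cv_auc=%.4f params={%s}", nm, tb$tuned[[nm]]$cv_auc,
         tb$tuned[[nm]]$candidate_table$params[
           which.max(tb$tuned[[nm]]$candidate_table$score)] %||% "")
  }

  ens_with <- build_ensemble(tb$tuned, tb$y, tb$encoder,
                             removal = removal_config(config$removal_threshold),
                             meta_seed = child_seed(config$seed, 4L))
  ens_without <- build_ensemble(tb$tuned, tb$y, tb$encoder, removal = NULL,
                                meta_seed = child_seed(config$seed, 4L))
  if (nrow(ens_with$ejection_log)) {
    note("ejected: %s", paste(ens_with$ejection_log$name, collapse = ", "))
  }
  tr <- ens_with$removal_trace
  if (nrow(tr$iterations)) {
    for (i in seq_len(nrow(tr$iterations))) {
      r <- tr$iterations[i, ]
      note("removal %d: pair (%s, %s) r=%.3f -> removed %s", i,
           r$learner_a, r$learner_b, r$max_corr, r$removed)
    }
  } else {
    note("removal: no pair above threshold %.2f", config$removal_threshold)
  }
  note("survivors: %s", paste(tr$survivors, collapse = ", "))

  x_test <- apply_encoder(tb$encoder, test)
  rows <- list()
  for (nm in names(ens_without$base_models)) {
    t <- ens_without$base_models[[nm]]
    p <- t$spec$predict_prob(t$fitted, x_test)
    rows[[nm]] <- c(classifier = nm,
                    metric_row(p, test$labels, config$threshold))
  }
  p_with <- predict_ensemble(ens_with, x_test)
  p_without <- predict_ensemble(ens_without, x_test)
  rows[["ensemble_with_removal"]] <-
    c(classifier = "ensemble_with_removal",
      metric_row(p_with, test$labels, config$threshold))
  rows[["ensemble_without_removal"]] <-
    c(classifier = "ensemble_without_removal",
      metric_row(p_without, test$labels, config$threshold))
  metrics <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(as.list(r), stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  for (cc in setdiff(names(metrics), "classifier")) {
    metrics[[cc]] <- as.numeric(metrics[[cc]])
  }

  imp <- NULL
  if (isTRUE(config$compute_importance %||% TRUE)) {
    imp <- build_importance_table(ens_with, tb$x, tb$y,
                                  lgr_tuned = tb$tuned[["lgr"]],
                                  seed = child_seed(config$seed, 3L),
                                  n_perm = config$importance_n_perm %||% 2L,
                                  max_rows = config$importance_max_rows %||% 1500L)
    note("knee index: %d of %d features", imp$knee_index, nrow(imp$table))
  }

  result <- list(metrics = metrics, ensemble_with = ens_with,
                 ensemble_without = ens_without, importance = imp,
                 removal_trace = tr, tuned = tb$tuned, split = split,
                 cohort = cohort, truth = src$truth, config = config,
                 encoder = tb$encoder, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    write_removal_trace(tr, file.path(out_dir, "removal_trace.json"))
    if (!is.null(imp)) {
      utils::write.csv(imp$table, file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
    }
    write_split(split, file.path(out_dir, "split.csv"))
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    if (!is.null(imp)) {
      grDevices::pdf(file.path(out_dir, "importance.pdf"), width = 7, height = 5)
      op <- graphics::par(mar = c(4, 11, 1, 1))
      plot_importance(imp)
      graphics::par(op)
      grDevices::dev.off()
    }
  }
  result
}

# One metric row, reported to 3 decimals with half-away-from-zero ties.
metric_row <- function(probs, labels, threshold) {
  m <- metrics_report(probs, labels, threshold)
  c(accuracy = round_half_up(m$accuracy, 3),
    sensitivity = round_half_up(m$sensitivity, 3),
    specificity = round_half_up(m$specificity, 3),
    balanced_accuracy = round_half_up(m$balanced_accuracy, 3),
    auc = round_half_up(m$auc, 3))
}
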