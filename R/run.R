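# Run orchestration: evaluate an enumerated grid, persist every model's
# interim results plus a machine-readable manifest, pick the final model
# (best validation AUC, then the one-standard-error rule within its
# component combination), and export the report files.

#' Cross-validate every enumerated pipeline on the training table
#'
#' When `run_dir` is given, each pipeline's interim results (per-case
#' held-out scores with fold ids and per-fold AUCs) are written to one
#' sub-folder per spec, and a manifest records the grid, seeds, and fold
#' assignments so any model can be reloaded for inspection.
#'
#' @param tab Labeled training [feature_table()].
#' @param specs List of `pipeline_spec`s (see [enumerate_pipelines()]).
#' @param k Folds (5 or 10).
#' @param seed Integer seed for the fold assignment.
#' @param run_dir Optional directory to persist the run into.
#' @param log Optional log object.
#' @return A `model_run`: list with `results` (cv_results in grid order),
#'   `specs`, `k`, `seed`, `run_dir`, `train_table`.
#' @export
run_pipelines <- function(tab, specs, k = 5L, seed = 1L, run_dir = NULL,
                          log = NULL) {
  stopifnot(inherits(tab, "feature_table"), length(specs) >= 1L)
  results <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    results[[i]] <- cross_validate(specs[[i]], tab, k = k, seed = seed)
    log_line(log, "evaluated ", spec_id(specs[[i]]), ": validation AUC ",
             sprintf("%.4f", results[[i]]$mean_val_auc))
  }
  run <- structure(list(results = results, specs = specs, k = k, seed = seed,
                        run_dir = run_dir, train_table = tab),
                   class = "model_run")
  if (!is.null(run_dir)) persist_run(run)
  run
}

#' @method print model_run
#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> %d pipelines, %d-fold CV, seed %d\n",
              length(x$specs), x$k, x$seed))
  invisible(x)
}

persist_run <- function(run) {
  dir.create(run$run_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in run$results) {
    d <- file.path(run$run_dir, spec_id(r$spec))
    dir.create(d, showWarnings = FALSE)
    utils::write.csv(data.frame(case_id = r$case_ids, fold = r$folds,
                                score = r$scores, label = r$labels),
                     file.path(d, "cv_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(fold = seq_len(r$k),
                                val_auc = r$fold_val_auc),
                     file.path(d, "fold_auc.csv"), row.names = FALSE)
  }
  manifest <- list(
    version = as.character(utils::packageVersion("radexplore")),
    timestamp = format(Sys.time(), tz = "UTC"),
    k = run$k, seed = run$seed,
    n_cases = length(run$train_table$case_ids),
    fold_assignment = stats::setNames(as.list(run$results[[1]]$folds),
                                      run$train_table$case_ids),
    specs = lapply(run$specs, function(s)
      s[c("normalizer", "reducer", "selector", "n_features", "classifier",
          "seed")]),
    spec_ids = vapply(run$specs, spec_id, ""),
    classifier_defaults = classifier_defaults(),
    mean_val_auc = vapply(run$results, function(r) r$mean_val_auc, 0))
  jsonlite::write_json(manifest, file.path(run$run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run$run_dir)
}

#' Pick the final model: best validation AUC, then the one-SE rule
#'
#' Ranks all pipelines by mean validation AUC; within the winning
#' component combination (same normalizer, reducer, selector, classifier)
#' the feature count is re-chosen by [one_se_select()] on its
#' AUC-versus-feature-count curve.
#'
#' @param run A `model_run`.
#' @param use_one_se Apply the one-standard-error rule (default `TRUE`).
#' @return List: `best` (top-AUC cv_result), `selected` (cv_result after
#'   the one-SE rule), `curve` (the winning combination's AUC curve),
#'   `ranked` (all cv_results ordered).
#' @export
select_model <- function(run, use_one_se = TRUE) {
  ranked <- rank_models(run$results)
  best <- ranked[[1]]
  combo_of <- function(s) paste(s$normalizer, s$reducer, s$selector,
                                s$classifier)
  combo <- combo_of(best$spec)
  group <- Filter(function(r) combo_of(r$spec) == combo, run$results)
  curve <- auc_curve(group)
  selected <- best
  if (use_one_se && nrow(curve) > 1) {
    n_sel <- one_se_select(curve)
    selected <- group[[which(vapply(group, function(r)
      r$spec$n_features, 0L) == n_sel)[1]]]
  }
  list(best = best, selected = selected, curve = curve, ranked = ranked)
}

#' Refit a cross-validated pipeline on the full training table and score it
#'
#' Computes clinical statistics on the training scores (Youden cutoff
#' chosen there), on the pooled held-out cross-validation scores
#' (validation), and — only for the final selected model, mirroring a
#' single use of the held-out dataset — on the test table. Evaluation of a
#' non-selected spec against test data requires `force = TRUE`.
#'
#' @param cv A `cv_result`.
#' @param train_tab The training [feature_table()] the CV ran on.
#' @param test_tab Optional held-out test [feature_table()].
#' @param is_selected Whether this spec is the final selected model.
#' @param force Override the selected-model guard.
#' @param n_boot,seed Bootstrap settings for the AUC confidence intervals.
#' @return A `model_result`: spec, per-dataset `stats`, `roc` points,
#'   `selected_features`, `coefficients`, the refit pipeline.
#' @export
evaluate_model <- function(cv, train_tab, test_tab = NULL,
                           is_selected = FALSE, force = FALSE,
                           n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(cv, "cv_result"))
  if (!is.null(test_tab) && !is_selected && !force)
    stop_input("test scoring is reserved for the final selected model; ",
               "pass force = TRUE to override")
  fitted <- fit_pipeline(cv$spec, train_tab$features, train_tab$labels)
  s_train <- predict_pipeline(fitted, train_tab$features)
  stats_train <- clinical_stats(s_train, train_tab$labels, n_boot = n_boot,
                                seed = seed)
  cutoff <- stats_train$cutoff
  stats <- list(train = stats_train)
  roc <- list(train = roc_points(s_train, train_tab$labels))
  stats$validation <- clinical_stats(cv$scores, cv$labels, cutoff = cutoff,
                                     n_boot = n_boot, seed = seed)
  roc$validation <- roc_points(cv$scores, cv$labels)
  if (!is.null(test_tab)) {
    s_test <- predict_pipeline(fitted, test_tab$features)
    stats$test <- clinical_stats(s_test, test_tab$labels, cutoff = cutoff,
                                 n_boot = n_boot, seed = seed)
    roc$test <- roc_points(s_test, test_tab$labels)
  }
  structure(list(spec = cv$spec, k = cv$k, stats = stats, roc = roc,
                 selected_features = fitted$selected_features,
                 coefficients = fitted$classifier$coefficients,
                 n_selected = fitted$effective_n_features,
                 fitted = fitted),
            class = "model_result")
}

#' @method print model_result
#' @export
print.model_result <- function(x, ...) {
  cat(describe_model(x), "\n")
  invisible(x)
}

#' Export the report files for a completed run
#'
#' Writes `results.csv` (one row per pipeline, ordered by validation AUC),
#' `roc_<spec>_<dataset>.csv` for the selected model,
#' `auc_curve_<spec>.csv` for the winning component combination,
#' `feature_histogram_<feature>.csv` (per-class values of each selected
#' feature), and `description.txt`. Idempotent: re-export overwrites with
#' identical content.
#'
#' @param run A `model_run`.
#' @param out_dir Output directory (created if missing).
#' @param test_tab Optional test [feature_table()]; scored only for the
#'   selected model.
#' @param use_one_se Apply the one-standard-error rule when selecting.
#' @param n_boot,seed Bootstrap settings.
#' @return Invisibly, a list with `selection`, `model` (the selected
#'   `model_result`), and `files` written.
#' @export
export_report <- function(run, out_dir, test_tab = NULL, use_one_se = TRUE,
                          n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(run, "model_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sel <- select_model(run, use_one_se = use_one_se)
  files <- character(0)
  res_df <- data.frame(
    rank = seq_along(sel$ranked),
    spec = vapply(sel$ranked, function(r) spec_id(r$spec), ""),
    n_features = vapply(sel$ranked, function(r) r$spec$n_features, 0L),
    mean_val_auc = vapply(sel$ranked, function(r) r$mean_val_auc, 0),
    se_val_auc = vapply(sel$ranked, function(r) r$se_val_auc, 0),
    mean_train_auc = vapply(sel$ranked, function(r) r$mean_train_auc, 0))
  f <- file.path(out_dir, "results.csv")
  utils::write.csv(res_df, f, row.names = FALSE)
  files <- c(files, f)
  model <- evaluate_model(sel$selected, run$train_table, test_tab,
                          is_selected = TRUE, n_boot = n_boot, seed = seed)
  id <- spec_id(model$spec)
  for (ds in names(model$roc)) {
    f <- file.path(out_dir, sprintf("roc_%s_%s.csv", id, ds))
    utils::write.csv(model$roc[[ds]], f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, sprintf("auc_curve_%s.csv", id))
  utils::write.csv(sel$curve, f, row.names = FALSE)
  files <- c(files, f)
  stats_rows <- do.call(rbind, lapply(names(model$stats), function(ds) {
    s <- model$stats[[ds]]
    data.frame(dataset = ds, auc = s$auc, ci_lo = s$ci_lo, ci_hi = s$ci_hi,
               accuracy = s$accuracy, sensitivity = s$sensitivity,
               specificity = s$specificity, cutoff = s$cutoff)
  }))
  f <- file.path(out_dir, sprintf("stats_%s.csv", id))
  utils::write.csv(stats_rows, f, row.names = FALSE)
  files <- c(files, f)
  # per-class value lists of the selected features, for histogram plots
  tr <- run$train_table
  for (i in seq_len(nrow(model$selected_features))) {
    fname <- model$selected_features$feature[i]
    if (!fname %in% tr$feature_names) next  # PCA components have no raw column
    f <- file.path(out_dir, sprintf("feature_histogram_%s.csv", fname))
    utils::write.csv(data.frame(case_id = tr$case_ids, label = tr$labels,
                                value = tr$features[, fname]),
                     f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "description.txt")
  writeLines(describe_model(model), f)
  files <- c(files, f)
  invisible(list(selection = sel, model = model, files = files))
}
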