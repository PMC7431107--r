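small_run <- function(td, seed = 1L) {
  tab <- make_table(table_spec(n_pos = 30, n_neg = 30, n_features = 12,
                               n_informative = 2, seed = 20))
  specs <- enumerate_pipelines(selectors = c("anova", "relief"),
                               classifiers = c("lda", "logistic_regression",
                                               "naive_bayes"),
                               feature_range = 2, seed = seed)
  run <- run_pipelines(tab, specs, k = 5, seed = seed, run_dir = td)
  list(tab = tab, run = run)
}

test_that("a run persists one sub-folder per pipeline plus a manifest", {
  td <- withr::local_tempdir()
  rr <- small_run(file.path(td, "run"))
  dirs <- list.dirs(file.path(td, "run"), recursive = FALSE)
  expect_length(dirs, 6L)
  man <- jsonlite::read_json(file.path(td, "run", "manifest.json"))
  expect_length(man$specs, 6L)
  expect_equal(man$k, 5L)
  expect_length(man$fold_assignment, 60L)
  sc <- read.csv(file.path(dirs[1], "cv_scores.csv"))
  expect_equal(nrow(sc), 60L)
  expect_setequal(names(sc), c("case_id", "fold", "score", "label"))
})

test_that("reruns with the same seed give identical rankings", {
  td <- withr::local_tempdir()
  a <- small_run(file.path(td, "a"))
  b <- small_run(file.path(td, "b"))
  expect_identical(vapply(rank_models(a$run$results), function(r) spec_id(r$spec), ""),
                   vapply(rank_models(b$run$results), function(r) spec_id(r$spec), ""))
  expect_identical(readLines(file.path(td, "a", "manifest.json"))[-3],
                   readLines(file.path(td, "b", "manifest.json"))[-3])  # timestamp differs
})

test_that("test scoring is guarded for non-selected models", {
  rr <- small_run(withr::local_tempdir())
  test_tab <- make_table(table_spec(n_pos = 10, n_neg = 10, n_features = 12,
                                    n_informative = 2, seed = 77))
  cv <- rr$run$results[[2]]
  expect_error(evaluate_model(cv, rr$tab, test_tab), "selected")
  expect_s3_class(evaluate_model(cv, rr$tab, test_tab, force = TRUE,
                                 n_boot = 50), "model_result")
  expect_s3_class(evaluate_model(cv, rr$tab, test_tab, is_selected = TRUE,
                                 n_boot = 50), "model_result")
})

test_that("the model description names every component and coefficient", {
  rr <- small_run(withr::local_tempdir())
  sel <- select_model(rr$run)
  model <- evaluate_model(sel$selected, rr$tab, is_selected = TRUE,
                          n_boot = 50)
  txt <- describe_model(model)
  spec <- model$spec
  for (part in c(spec$normalizer, spec$reducer, spec$selector, spec$classifier,
                 "cross-validation", "AUC", "sensitivity"))
    expect_match(txt, part, fixed = TRUE)
  n_coef_lines <- length(grep("coefficient", strsplit(txt, "\n")[[1]]))
  if (!is.null(model$coefficients))
    expect_equal(n_coef_lines, model$n_selected)
  expect_identical(txt, describe_model(model))
})

test_that("exported statistics re-parse to the stored values, idempotently", {
  td <- withr::local_tempdir()
  rr <- small_run(file.path(td, "run"))
  test_tab <- make_table(table_spec(n_pos = 10, n_neg = 10, n_features = 12,
                                    n_informative = 2, seed = 78))
  rep1 <- export_report(rr$run, file.path(td, "rep"), test_tab = test_tab,
                        n_boot = 50, seed = 4)
  res <- read.csv(file.path(td, "rep", "results.csv"))
  expect_equal(nrow(res), 6L)
  expect_true(all(diff(res$mean_val_auc) <= 1e-12))
  expect_equal(res$mean_val_auc,
               vapply(rep1$selection$ranked, function(r) r$mean_val_auc, 0))
  id <- spec_id(rep1$model$spec)
  st <- read.csv(file.path(td, "rep", sprintf("stats_%s.csv", id)))
  expect_setequal(st$dataset, c("train", "validation", "test"))
  expect_equal(st$auc[st$dataset == "test"], rep1$model$stats$test$auc)
  # re-export overwrites with identical content
  files1 <- sort(list.files(file.path(td, "rep")))
  before <- lapply(file.path(td, "rep", files1), readLines)
  export_report(rr$run, file.path(td, "rep"), test_tab = test_tab,
                n_boot = 50, seed = 4)
  after <- lapply(file.path(td, "rep", files1), readLines)
  expect_identical(before, after)
})

test_that("the prepare command writes the stratified files and audit log", {
  td <- withr::local_tempdir()
  tab <- make_imbalanced_table()
  write_table_csv(tab, file.path(td, "all.csv"))
  cmd_prepare(file.path(td, "all.csv"), file.path(td, "prep"),
              test_fraction = 0.3, seed = 1)
  train <- read.csv(file.path(td, "prep", "train.csv"))
  expect_equal(nrow(train), 177L)
  expect_equal(nrow(read.csv(file.path(td, "prep", "test.csv"))), 75L)
  expect_true(file.exists(file.path(td, "prep", "audit.log")))
  # same seed reproduces the same files
  cmd_prepare(file.path(td, "all.csv"), file.path(td, "prep2"),
              test_fraction = 0.3, seed = 1)
  expect_identical(readLines(file.path(td, "prep", "train.csv")),
                   readLines(file.path(td, "prep2", "train.csv")))
})

test_that("the report command emits test metrics only for the selected model", {
  td <- withr::local_tempdir()
  tab <- make_table(table_spec(n_pos = 30, n_neg = 30, n_features = 10,
                               n_informative = 2, seed = 21))
  write_table_csv(tab, file.path(td, "train.csv"))
  test_tab <- make_table(table_spec(n_pos = 12, n_neg = 12, n_features = 10,
                                    n_informative = 2, seed = 22))
  write_table_csv(test_tab, file.path(td, "test.csv"))
  run <- cmd_run(file.path(td, "train.csv"), file.path(td, "run"),
                 config = list(selectors = c("anova", "relief"),
                               classifiers = c("lda", "naive_bayes"),
                               feature_range = c(2, 2), k = 5, seed = 1))
  cmd_report(run, file.path(td, "rep"), test_csv = file.path(td, "test.csv"))
  stats_files <- list.files(file.path(td, "rep"), pattern = "^stats_")
  expect_length(stats_files, 1L)  # only the selected spec is test-scored
  roc_test <- list.files(file.path(td, "rep"), pattern = "^roc_.*_test[.]csv$")
  expect_length(roc_test, 1L)
  # without a test table no test rows appear
  cmd_report(run, file.path(td, "rep2"))
  st <- read.csv(file.path(td, "rep2",
                           list.files(file.path(td, "rep2"), pattern = "^stats_")))
  expect_false("test" %in% st$dataset)
})
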