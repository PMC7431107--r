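test_that("AUC follows the Mann-Whitney identity with half-credit ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(6:15, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force some ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
    # monotone-transform invariance and complement symmetry
    expect_equal(roc_auc(exp(3 * s), y), roc_auc(s, y))
    st <- s + seq_len(n) * 1e-9  # break ties
    expect_equal(roc_auc(st, y) + roc_auc(-st, y), 1)
  }
})

test_that("AUC equals the trapezoidal area under the empirical ROC", {
  skip_if_not_installed("pROC")
  set.seed(4)
  s <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("the bootstrap interval brackets the point AUC and is seeded", {
  set.seed(5)
  for (seed in 1:5) {
    set.seed(seed)
    s <- rnorm(60)
    y <- rbinom(60, 1, 0.5)
    if (min(table(y)) < 2) next
    ci <- bootstrap_auc_ci(s, y, n_boot = 400, seed = seed)
    a <- roc_auc(s, y)
    expect_lte(ci[1], a + 0.02)
    expect_gte(ci[2], a - 0.02)
    expect_identical(ci, bootstrap_auc_ci(s, y, n_boot = 400, seed = seed))
  }
  # perfect separation collapses the upper end to 1
  s <- c(rep(0.9, 30), rep(0.1, 30))
  y <- rep(c(1, 0), each = 30)
  ci <- bootstrap_auc_ci(s, y, n_boot = 200, seed = 1)
  expect_equal(unname(ci[2]), 1.0)
  expect_gt(ci[1], 0.99)
})

test_that("Youden-cutoff metrics match exhaustive cutoff search", {
  s <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  y <- c(0, 0, 1, 0, 1, 1)
  got <- threshold_metrics(s, y)
  # brute force over all cutoffs
  best_j <- -Inf; best <- NULL
  for (c in sort(unique(s))) {
    sens <- mean(s[y == 1] >= c); spec <- mean(s[y == 0] < c)
    if (sens + spec - 1 > best_j + 1e-12) {
      best_j <- sens + spec - 1
      best <- list(acc = mean((s >= c) == y), sens = sens, spec = spec, cut = c)
    }
  }
  expect_equal(got$accuracy, best$acc)
  expect_equal(got$sensitivity, best$sens)
  expect_equal(got$specificity, best$spec)
  expect_equal(got$cutoff, best$cut)
  # perfect scorer
  perf <- threshold_metrics(y, y)
  expect_equal(c(perf$accuracy, perf$sensitivity, perf$specificity), c(1, 1, 1))
  # anti-correlated scorer still yields a well-defined cutoff
  flip <- threshold_metrics(1 - y, y)
  expect_true(is.finite(flip$cutoff))
})

test_that("a training cutoff is reused verbatim downstream", {
  s_train <- c(0.2, 0.4, 0.6, 0.8)
  y_train <- c(0, 0, 1, 1)
  cut <- threshold_metrics(s_train, y_train)$cutoff
  m <- threshold_metrics(c(0.5, 0.7), c(0, 1), cutoff = cut)
  expect_equal(m$cutoff, cut)
})

test_that("models rank by validation AUC with a fewer-features tie-break", {
  mk <- function(auc, nf) structure(list(mean_val_auc = auc,
                                         spec = pipeline_spec(n_features = nf)),
                                    class = "cv_result")
  ranked <- rank_models(list(mk(0.7, 3), mk(0.9, 5), mk(0.8, 2)))
  expect_equal(vapply(ranked, function(r) r$mean_val_auc, 0), c(0.9, 0.8, 0.7))
  tied <- rank_models(list(mk(0.8, 15), mk(0.8, 4)))
  expect_equal(tied[[1]]$spec$n_features, 4L)
  expect_setequal(attr(ranked, "order"), 1:3)
})

test_that("the one-standard-error rule matches its direct evaluation", {
  curve <- data.frame(n_features = c(1, 4, 15),
                      mean_auc = c(0.80, 0.81, 0.82),
                      se = c(0.01, 0.01, 0.015))
  expect_equal(one_se_select(curve), 4)   # 0.80 < 0.805 <= 0.81
  inc <- data.frame(n_features = 1:5, mean_auc = seq(0.6, 0.9, length.out = 5),
                    se = rep(1e-6, 5))
  expect_equal(one_se_select(inc), 5)
  flat <- data.frame(n_features = c(2, 7, 9), mean_auc = rep(0.7, 3),
                     se = rep(0.01, 3))
  expect_equal(one_se_select(flat), 2)
  # never exceeds the argmax
  set.seed(6)
  for (i in 1:10) {
    cv <- data.frame(n_features = 1:8, mean_auc = runif(8, 0.5, 0.9),
                     se = runif(8, 0, 0.05))
    expect_lte(one_se_select(cv), cv$n_features[which.max(cv$mean_auc)])
  }
})
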