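# Clinical statistics and model selection: AUC by the Mann-Whitney
# identity, percentile-bootstrap confidence intervals, Youden-cutoff
# accuracy/sensitivity/specificity, ranking by validation AUC, and the
# one-standard-error rule.

#' Area under the ROC curve
#'
#' The Mann-Whitney U identity: the fraction of (positive, negative) score
#' pairs in which the positive outranks the negative, ties counting one
#' half — identical to the trapezoidal area under the empirical ROC.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Binary 0/1 vector; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC points
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame of `(fpr, tpr, cutoff)` over all distinct cutoffs,
#'   from (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  tpr <- vapply(cuts, function(c) sum(scores >= c & labels == 1L) / n1, 0)
  fpr <- vapply(cuts, function(c) sum(scores >= c & labels == 0L) / n0, 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr), cutoff = c(Inf, cuts))
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Stratified case resampling with replacement (each class resampled
#' within itself, so no resample is degenerate); the percentile interval
#' at `(1 - level) / 2` on each side. Deterministic under the seed.
#'
#' @param scores,labels As in [roc_auc()]; each class needs >= 2 cases.
#' @param n_boot Number of resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 1000L, level = 0.95,
                             seed = 1L) {
  labels <- as.integer(labels)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (length(i1) < 2L || length(i0) < 2L)
    stop_input("each class needs at least 2 cases to resample")
  aucs <- with_seed(derive_seed(seed, "boot"), {
    vapply(seq_len(n_boot), function(b) {
      r1 <- sample(i1, replace = TRUE)
      r0 <- sample(i0, replace = TRUE)
      roc_auc(scores[c(r1, r0)], labels[c(r1, r0)])
    }, 0)
  })
  alpha <- (1 - level) / 2
  unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
}

#' Accuracy, sensitivity, specificity at the Youden cutoff
#'
#' The cutoff maximizing Youden's J = sensitivity + specificity - 1 over
#' the observed scores (predicted positive when `score >= cutoff`); ties
#' take the lowest cutoff. Pass a `cutoff` to reuse a training cutoff on
#' validation or test scores.
#'
#' @param scores,labels As in [roc_auc()].
#' @param cutoff Optional fixed cutoff; when `NULL`, chosen by Youden's J.
#' @return List `accuracy`, `sensitivity`, `specificity`, `cutoff`.
#' @export
threshold_metrics <- function(scores, labels, cutoff = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop_input("both classes must be present")
  if (is.null(cutoff)) {
    cand <- sort(unique(scores))
    j <- vapply(cand, function(c) {
      sens <- mean(scores[labels == 1L] >= c)
      spec <- mean(scores[labels == 0L] < c)
      sens + spec - 1
    }, 0)
    cutoff <- cand[which(j == max(j))[1]]  # ties: lowest cutoff
  }
  pred <- as.integer(scores >= cutoff)
  list(accuracy = mean(pred == labels),
       sensitivity = mean(pred[labels == 1L] == 1L),
       specificity = mean(pred[labels == 0L] == 0L),
       cutoff = cutoff)
}

#' Full clinical statistics for one score vector
#'
#' @param scores,labels As in [roc_auc()].
#' @param cutoff Optional fixed cutoff (see [threshold_metrics()]).
#' @param n_boot,level,seed Passed to [bootstrap_auc_ci()].
#' @return List `auc`, `ci` (lo, hi), `accuracy`, `sensitivity`,
#'   `specificity`, `cutoff`.
#' @export
clinical_stats <- function(scores, labels, cutoff = NULL, n_boot = 1000L,
                           level = 0.95, seed = 1L) {
  auc <- roc_auc(scores, labels)
  ci <- bootstrap_auc_ci(scores, labels, n_boot = n_boot, level = level,
                         seed = seed)
  tm <- threshold_metrics(scores, labels, cutoff = cutoff)
  c(list(auc = auc, ci_lo = ci[1], ci_hi = ci[2]), tm)
}

#' Order cross-validation results by validation AUC
#'
#' Descending mean validation AUC; ties broken by fewer features, then by
#' input order. A permutation of the input — nothing is dropped.
#'
#' @param results List of `cv_result`s.
#' @return The reordered list, with attribute `order` (the permutation).
#' @export
rank_models <- function(results) {
  if (length(results) == 0L) stop_input("no results to rank")
  auc <- vapply(results, function(r) r$mean_val_auc, 0)
  nf <- vapply(results, function(r) r$spec$n_features, 0L)
  ord <- order(-auc, nf, seq_along(results))
  out <- results[ord]
  attr(out, "order") <- ord
  out
}

#' One-standard-error rule on an AUC-versus-feature-count curve
#'
#' Let `n*` maximize the mean validation AUC; return the smallest feature
#' count whose mean AUC is within one standard error (the SE at `n*`) of
#' the maximum. Never exceeds `n*`; a constant curve returns the smallest
#' count.
#'
#' @param curve Data frame with columns `n_features`, `mean_auc`, `se`.
#' @return The chosen feature count.
#' @export
one_se_select <- function(curve) {
  stopifnot(all(c("n_features", "mean_auc", "se") %in% names(curve)),
            nrow(curve) >= 1)
  curve <- curve[order(curve$n_features), , drop = FALSE]
  best <- which.max(curve$mean_auc)
  thr <- curve$mean_auc[best] - curve$se[best]
  curve$n_features[which(curve$mean_auc >= thr)[1]]
}

#' Build the AUC-versus-feature-count curve for one component combination
#'
#' @param results List of `cv_result`s sharing normalizer, reducer,
#'   selector, and classifier, differing in `n_features`.
#' @return Data frame `n_features`, `mean_auc`, `se`, sorted.
#' @export
auc_curve <- function(results) {
  df <- data.frame(
    n_features = vapply(results, function(r) r$spec$n_features, 0L),
    mean_auc = vapply(results, function(r) r$mean_val_auc, 0),
    se = vapply(results, function(r) r$se_val_auc, 0))
  df[order(df$n_features), , drop = FALSE]
}

#' One-paragraph description of a developed model
#'
#' Names every pipeline component, the cross-validation scheme, the
#' per-dataset statistics, and lists the selected features with their
#' selector scores and (for linear classifiers) coefficients.
#'
#' @param model A `model_result` from [evaluate_model()].
#' @return Character scalar (deterministic for a given result).
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "model_result"))
  spec <- model$spec
  lines <- sprintf(paste0(
    "The model normalizes features by %s normalization, reduces dimension ",
    "by %s, selects %d feature(s) by %s, and classifies with %s. ",
    "It was developed with stratified %d-fold cross-validation."),
    spec$normalizer, spec$reducer, model$n_selected, spec$selector,
    spec$classifier, model$k)
  for (ds in names(model$stats)) {
    s <- model$stats[[ds]]
    lines <- c(lines, sprintf(
      "On the %s dataset: AUC %.3f (95%% CI %.3f-%.3f), accuracy %.3f, sensitivity %.3f, specificity %.3f.",
      ds, s$auc, s$ci_lo, s$ci_hi, s$accuracy, s$sensitivity, s$specificity))
  }
  sf <- model$selected_features
  for (i in seq_len(nrow(sf))) {
    coef_txt <- if (!is.null(model$coefficients))
      sprintf(", coefficient %.4g", model$coefficients[i]) else ""
    lines <- c(lines, sprintf("  feature %s: selector score %.4g%s",
                              sf$feature[i], sf$score[i], coef_txt))
  }
  paste(lines, collapse = "\n")
}
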