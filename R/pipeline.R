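# Pipeline assembly: one spec = {normalizer, reducer, selector,
# feature count, classifier, seed}. Enumeration builds the full Cartesian
# grid; cross-validation refits every stage inside each training fold so
# no statistic ever sees a held-out case.

NORMALIZERS <- c("minmax", "zscore", "mean")
REDUCERS <- c("pcc", "pca", "none")
SELECTORS <- c("anova", "rfe", "relief", "none")

#' Construct one pipeline specification
#'
#' @param normalizer One of `"minmax"`, `"zscore"`, `"mean"`.
#' @param reducer One of `"pcc"`, `"pca"`, `"none"`.
#' @param selector One of `"anova"`, `"rfe"`, `"relief"`, `"none"`.
#' @param n_features Features kept by the selector (ignored when the
#'   selector is `"none"`, which keeps everything).
#' @param classifier One of the kinds in [fit_classifier()].
#' @param seed Integer seed governing every stochastic component.
#' @param params Optional per-classifier hyper-parameter overrides.
#' @return A `pipeline_spec`.
#' @export
pipeline_spec <- function(normalizer = "zscore", reducer = "pcc",
                          selector = "anova", n_features = 1L,
                          classifier = "lda", seed = 1L, params = list()) {
  normalizer <- match.arg(normalizer, NORMALIZERS)
  reducer <- match.arg(reducer, REDUCERS)
  selector <- match.arg(selector, SELECTORS)
  classifier <- match.arg(classifier, CLASSIFIER_KINDS)
  if (n_features < 1L) stop_input("n_features must be >= 1")
  structure(list(normalizer = normalizer, reducer = reducer,
                 selector = selector, n_features = as.integer(n_features),
                 classifier = classifier, seed = as.integer(seed),
                 params = params),
            class = "pipeline_spec")
}

#' Short identifier of a pipeline spec
#' @param spec A `pipeline_spec`.
#' @return Character scalar like `"zscore_pcc_anova_4_lda"`.
#' @export
spec_id <- function(spec) {
  paste(spec$normalizer, spec$reducer, spec$selector, spec$n_features,
        spec$classifier, sep = "_")
}

#' @method print pipeline_spec
#' @export
print.pipeline_spec <- function(x, ...) {
  cat("<pipeline_spec>", spec_id(x), "seed", x$seed, "\n")
  invisible(x)
}

#' Enumerate every combination of the selected pipeline components
#'
#' The full Cartesian product of the per-stage menus crossed with each
#' feature count, in stable normalizer-major order (normalizer outermost,
#' feature count innermost). Two selectors crossed with three classifiers
#' give six pipelines; three by four give twelve.
#'
#' @param normalizers,reducers,selectors,classifiers Character vectors of
#'   stage selections (each nonempty).
#' @param feature_range Integer vector of feature counts to sweep.
#' @param seed Seed stored in every spec.
#' @param params Per-classifier hyper-parameter overrides.
#' @return List of `pipeline_spec`s of length
#'   `prod(stage sizes) * length(feature_range)`.
#' @export
enumerate_pipelines <- function(normalizers = "zscore", reducers = "pcc",
                                selectors = c("anova", "rfe", "relief"),
                                classifiers = c("svm", "lda",
                                                "random_forest",
                                                "logistic_regression"),
                                feature_range = 1:20, seed = 1L,
                                params = list()) {
  for (menu in list(normalizers, reducers, selectors, classifiers,
                    feature_range))
    if (length(menu) == 0L) stop_input("every stage menu must be nonempty")
  specs <- list()
  for (nm in normalizers) for (rd in reducers) for (sl in selectors)
    for (cl in classifiers) for (nf in feature_range) {
      specs[[length(specs) + 1L]] <-
        pipeline_spec(nm, rd, sl, nf, cl, seed = seed,
                      params = params[[cl]] %||% list())
    }
  specs
}

#' Fit every stage of one pipeline on training data
#'
#' Stages run in order: normalizer, reducer, selector, classifier. The
#' selector keeps the top `n_features` ranked features (capped at the
#' number surviving reduction; the effective count is recorded); selector
#' `"none"` keeps all. The returned object re-applies the identical fitted
#' transform to new data, so applying it to its own training rows
#' reproduces the matrix the classifier saw.
#'
#' @param spec A `pipeline_spec`.
#' @param X Training matrix.
#' @param y Binary 0/1 labels.
#' @param log Optional log object.
#' @return A `fitted_pipeline` with `selected_features` (name, score) and
#'   classifier `coefficients` when linear.
#' @export
fit_pipeline <- function(spec, X, y, log = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  norm <- normalize_fit_apply(X, spec$normalizer, log = log)
  Z <- norm$transformed
  red_state <- NULL
  if (spec$reducer == "pcc") {
    red <- pcc_reduce(Z, threshold = 0.9, seed = spec$seed)
    red_state <- list(kind = "pcc", kept = red$kept)
    Z <- red$transformed
  } else if (spec$reducer == "pca") {
    ncomp <- min(nrow(Z) - 1L, ncol(Z))
    red <- pca_reduce(Z, ncomp)
    red_state <- list(kind = "pca", state = red$state)
    Z <- red$transformed
    colnames(Z) <- sprintf("PC%d", seq_len(ncol(Z)))
  } else {
    red_state <- list(kind = "none")
  }
  avail <- ncol(Z)
  nf <- min(spec$n_features, avail)
  ranking <- switch(spec$selector,
    anova = anova_rank(Z, y, log = log),
    relief = relief_rank(Z, y, seed = spec$seed),
    rfe = rfe_rank(Z, y, n_features = nf),
    none = data.frame(feature = colnames(Z), score = NA_real_,
                      column = seq_len(avail)))
  keep <- if (spec$selector == "none") seq_len(avail) else
    ranking$column[seq_len(nf)]
  sel <- Z[, keep, drop = FALSE]
  clf <- fit_classifier(sel, y, spec$classifier, seed = spec$seed,
                        params = spec$params)
  selected <- ranking[match(keep, ranking$column),
                      c("feature", "score"), drop = FALSE]
  rownames(selected) <- NULL
  structure(list(spec = spec, normalizer_state = norm$state,
                 reducer_state = red_state, selected_columns = keep,
                 selected_features = selected, classifier = clf,
                 effective_n_features = length(keep),
                 feature_names = colnames(X)),
            class = "fitted_pipeline")
}

#' Transform new cases through a fitted pipeline
#'
#' @param fitted A `fitted_pipeline`.
#' @param X Matrix with the training columns.
#' @return The matrix the classifier scores (post normalization,
#'   reduction, selection).
#' @export
transform_pipeline <- function(fitted, X) {
  Z <- apply_normalizer(fitted$normalizer_state, as.matrix(X))
  rs <- fitted$reducer_state
  if (rs$kind == "pcc") Z <- Z[, rs$kept, drop = FALSE]
  if (rs$kind == "pca") {
    Z <- apply_reducer_pca(rs$state, Z)
    colnames(Z) <- sprintf("PC%d", seq_len(ncol(Z)))
  }
  Z[, fitted$selected_columns, drop = FALSE]
}

#' Score new cases with a fitted pipeline
#'
#' @param fitted A `fitted_pipeline`.
#' @param X Matrix with the training columns.
#' @return Class-1 scores in `[0, 1]`. Uses only the feature values; the
#'   labels of the scored cases play no role.
#' @export
predict_pipeline <- function(fitted, X) {
  predict_classifier(fitted$classifier, transform_pipeline(fitted, X))
}

#' Assign stratified cross-validation folds
#'
#' Each class is shuffled by the seeded stream and dealt round-robin over
#' `k` folds, so every fold preserves the class ratio up to one case.
#'
#' @param y Binary 0/1 labels.
#' @param k Number of folds (5 or 10 in practice).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  if (min(table(factor(y, levels = 0:1))) < k)
    stop_input("each class needs at least k = ", k, " cases")
  folds <- integer(length(y))
  for (cls in c(0L, 1L)) {
    idx <- which(y == cls)
    sh <- with_seed(derive_seed(seed, paste0("fold", cls)), sample(idx))
    folds[sh] <- rep_len(seq_len(k), length(sh))
  }
  folds
}

#' Evaluate one pipeline by stratified k-fold cross-validation
#'
#' Every stage (normalizer, reducer, selector, classifier) is fit on the
#' k-1 training folds only and applied to the held-out fold. Returns the
#' per-fold validation AUCs, their mean and standard error
#' (`sd / sqrt(k)`), the mean training AUC, and the held-out scores for
#' every case (each case is held out exactly once).
#'
#' @param spec A `pipeline_spec`.
#' @param tab A labeled training [feature_table()].
#' @param k Number of folds, 5 or 10.
#' @param seed Integer seed for the fold assignment.
#' @return A `cv_result`.
#' @export
cross_validate <- function(spec, tab, k = 5L, seed = 1L) {
  stopifnot(inherits(tab, "feature_table"))
  if (!k %in% c(5L, 10L)) stop_input("k must be 5 or 10")
  if (anyNA(tab$labels)) stop_input("table has unlabeled cases")
  folds <- stratified_folds(tab$labels, k, seed)
  val_auc <- train_auc <- numeric(k)
  scores <- numeric(length(folds))
  for (f in seq_len(k)) {
    tr <- folds != f
    fitted <- fit_pipeline(spec, tab$features[tr, , drop = FALSE],
                           tab$labels[tr])
    s_val <- predict_pipeline(fitted, tab$features[!tr, , drop = FALSE])
    s_tr <- predict_pipeline(fitted, tab$features[tr, , drop = FALSE])
    scores[!tr] <- s_val
    val_auc[f] <- roc_auc(s_val, tab$labels[!tr])
    train_auc[f] <- roc_auc(s_tr, tab$labels[tr])
  }
  structure(list(spec = spec, k = k, seed = seed, folds = folds,
                 fold_val_auc = val_auc,
                 mean_val_auc = mean(val_auc),
                 se_val_auc = stats::sd(val_auc) / sqrt(k),
                 mean_train_auc = mean(train_auc),
                 scores = scores, labels = tab$labels,
                 case_ids = tab$case_ids),
            class = "cv_result")
}

#' @method print cv_result
#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: validation AUC %.3f (SE %.3f), training AUC %.3f\n",
              spec_id(x$spec), x$mean_val_auc, x$se_val_auc, x$mean_train_auc))
  invisible(x)
}
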