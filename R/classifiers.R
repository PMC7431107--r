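# Stage 4: classifiers. Every kind is fit through one entry point and
# scored through one predict contract: a probability-like score in [0, 1],
# monotone in the likelihood of class 1. Linear kinds expose per-feature
# coefficients for the model report. Hyper-parameters are pinned defaults,
# overridable per run and recorded in the manifest.

CLASSIFIER_KINDS <- c("logistic_regression", "lasso", "svm", "lda",
                      "decision_tree", "random_forest", "adaboost",
                      "gaussian_process", "naive_bayes", "mlp")

#' Default hyper-parameters for each classifier kind
#'
#' @return Named list of parameter lists.
#' @export
classifier_defaults <- function() {
  list(logistic_regression = list(),
       lasso = list(lambda = 0.05),
       svm = list(kernel = "linear", cost = 1),
       lda = list(),
       decision_tree = list(maxdepth = 30L, cp = 0.01),
       random_forest = list(ntree = 200L),
       adaboost = list(n_rounds = 50L),
       gaussian_process = list(),
       naive_bayes = list(),
       mlp = list(size = 5L, decay = 0.01, maxit = 200L))
}

#' Fit a classifier with a probability-scoring contract
#'
#' @param X Numeric training matrix.
#' @param y Binary 0/1 vector (both classes required).
#' @param kind One of `"logistic_regression"`, `"lasso"`, `"svm"`,
#'   `"lda"`, `"decision_tree"`, `"random_forest"`, `"adaboost"`,
#'   `"gaussian_process"`, `"naive_bayes"`, `"mlp"`.
#' @param seed Integer seed; every stochastic fit is wrapped in it.
#' @param params Named list overriding [classifier_defaults()] entries.
#' @return A `fitted_classifier` with fields `kind`, `model`,
#'   `coefficients` (named vector for linear kinds, else `NULL`), `params`.
#' @export
fit_classifier <- function(X, y, kind, seed = 1L, params = list()) {
  kind <- match.arg(kind, CLASSIFIER_KINDS)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("V%d", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_input("training labels hold a single class")
  pars <- utils::modifyList(classifier_defaults()[[kind]], params)
  yf <- factor(y, levels = c(0L, 1L))
  sd_fit <- derive_seed(seed, kind)
  model <- coefs <- NULL
  if (kind == "logistic_regression") {
    fit <- suppressWarnings(stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                                           family = stats::binomial()))
    model <- fit$coefficients
    coefs <- model[-1]
  } else if (kind == "lasso") {
    fit <- with_seed(sd_fit, glmnet::glmnet(X, yf, family = "binomial",
                                            alpha = 1, lambda = pars$lambda))
    model <- fit
    cf <- as.matrix(stats::coef(fit))[, 1]
    coefs <- cf[-1]
  } else if (kind == "svm") {
    model <- with_seed(sd_fit,
      e1071::svm(X, yf, kernel = pars$kernel, cost = pars$cost,
                 probability = TRUE))
    if (identical(pars$kernel, "linear")) {
      w <- t(model$coefs) %*% model$SV
      coefs <- stats::setNames(as.numeric(w), colnames(X))
    }
  } else if (kind == "lda") {
    model <- suppressWarnings(MASS::lda(X, grouping = yf))
    coefs <- stats::setNames(as.numeric(model$scaling[, 1]), colnames(X))
  } else if (kind == "decision_tree") {
    df <- data.frame(X, check.names = FALSE)
    df$.y <- yf
    model <- with_seed(sd_fit,
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(maxdepth = pars$maxdepth,
                                                  cp = pars$cp)))
  } else if (kind == "random_forest") {
    model <- with_seed(sd_fit,
      randomForest::randomForest(X, yf, ntree = pars$ntree))
  } else if (kind == "adaboost") {
    model <- with_seed(sd_fit, fit_adaboost(X, y, pars$n_rounds))
  } else if (kind == "gaussian_process") {
    model <- with_seed(sd_fit, {
      out <- utils::capture.output(
        m <- kernlab::gausspr(X, yf, type = "classification"))
      m
    })
  } else if (kind == "naive_bayes") {
    model <- e1071::naiveBayes(X, yf)
  } else if (kind == "mlp") {
    model <- with_seed(sd_fit,
      nnet::nnet(X, y, size = pars$size, decay = pars$decay,
                 maxit = pars$maxit, trace = FALSE, entropy = TRUE))
  }
  structure(list(kind = kind, model = model, coefficients = coefs,
                 params = pars, feature_names = colnames(X)),
            class = "fitted_classifier")
}

#' Score new cases with a fitted classifier
#'
#' @param fit A `fitted_classifier`.
#' @param X Matrix with the training columns.
#' @return Numeric vector of class-1 scores in `[0, 1]`.
#' @export
predict_classifier <- function(fit, X) {
  stopifnot(inherits(fit, "fitted_classifier"))
  X <- as.matrix(X)
  colnames(X) <- fit$feature_names
  kind <- fit$kind
  p <- switch(kind,
    logistic_regression = as.numeric(stats::plogis(cbind(1, X) %*% fit$model)),
    lasso = as.numeric(stats::predict(fit$model, X, type = "response")),
    svm = {
      pr <- stats::predict(fit$model, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    lda = {
      post <- stats::predict(fit$model, X)$posterior
      post[, "1"]
    },
    decision_tree = {
      pr <- stats::predict(fit$model, data.frame(X, check.names = FALSE),
                           type = "prob")
      pr[, "1"]
    },
    random_forest = stats::predict(fit$model, X, type = "prob")[, "1"],
    adaboost = predict_adaboost(fit$model, X),
    gaussian_process = {
      pr <- kernlab::predict(fit$model, X, type = "probabilities")
      pr[, colnames(pr) == "1"]
    },
    naive_bayes = stats::predict(fit$model, X, type = "raw")[, "1"],
    mlp = as.numeric(stats::predict(fit$model, X))
  )
  pmin(pmax(as.numeric(p), 0), 1)
}

# Discrete AdaBoost (SAMME with two classes) over decision stumps.
fit_adaboost <- function(X, y, n_rounds) {
  n <- nrow(X)
  y_pm <- ifelse(y == 1L, 1, -1)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  df <- data.frame(X, check.names = FALSE)
  for (m in seq_len(n_rounds)) {
    df$.y <- factor(y, levels = 0:1)
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = rpart::rpart.control(maxdepth = 1,
                                                         cp = -1, xval = 0,
                                                         minsplit = 2))
    pred <- ifelse(stats::predict(stump, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != y_pm))
    if (err >= 0.5 || length(stump$splits) == 0L) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    w <- w * exp(-alpha * y_pm * pred)
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    if (err < 1e-9) break
  }
  if (length(stumps) == 0L) {
    # no usable split: fall back to the class prior
    return(list(stumps = list(), alphas = numeric(0), prior = mean(y)))
  }
  list(stumps = stumps, alphas = alphas, prior = mean(y))
}

predict_adaboost <- function(model, X) {
  if (length(model$stumps) == 0L) return(rep(model$prior, nrow(X)))
  df <- data.frame(X, check.names = FALSE)
  margin <- rep(0, nrow(X))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[m]], df, type = "class") == "1",
                   1, -1)
    margin <- margin + model$alphas[m] * pred
  }
  (margin / sum(model$alphas) + 1) / 2
}
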