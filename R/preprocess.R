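# Stage 1 and 2 of the pipeline: per-feature normalization and dimension
# reduction. Each fit returns a state that re-applies the training
# statistics to new data, so held-out folds never inform the transform.

#' Fit a per-feature normalizer on training data and apply it
#'
#' Methods: `zscore` is `(x - mean) / sd` (population sd); `minmax` is
#' `(x - min) / (max - min)`; `mean` is `(x - mean) / (max - min)`. A
#' feature with zero spread maps to all zeros (logged), never `NaN`.
#'
#' @param X Numeric training matrix (rows = cases).
#' @param method `"zscore"`, `"minmax"`, or `"mean"`.
#' @param log Optional log object.
#' @return List with `state` (location/scale per feature) and `transformed`.
#' @export
normalize_fit_apply <- function(X, method = c("zscore", "minmax", "mean"),
                                log = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_input("need at least 2 rows to fit a normalizer")
  mu <- colMeans(X)
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  location <- switch(method, zscore = mu, minmax = mn, mean = mu)
  scale <- switch(method, zscore = sd_pop, minmax = mx - mn, mean = mx - mn)
  degenerate <- scale == 0
  if (any(degenerate))
    log_line(log, "constant feature(s) mapped to zero by ", method,
             " normalization: ",
             paste(colnames(X)[degenerate] %||% which(degenerate), collapse = ", "))
  scale[degenerate] <- 1  # output becomes (x - x) / 1 = 0
  location[degenerate] <- mu[degenerate]
  state <- list(method = method, location = location, scale = scale)
  list(state = state, transformed = apply_normalizer(state, X))
}

#' Apply a fitted normalizer to new data
#'
#' @param state State from [normalize_fit_apply()].
#' @param X Matrix with the same columns as the training data.
#' @return Transformed matrix.
#' @export
apply_normalizer <- function(state, X) {
  sweep(sweep(as.matrix(X), 2, state$location), 2, state$scale, `/`)
}

#' Redundancy filter on the Pearson correlation coefficient
#'
#' Scans surviving feature pairs in a seeded random order; whenever the
#' absolute Pearson correlation of a pair exceeds `threshold`, one member
#' (chosen by the seeded stream) is removed. Afterwards no surviving pair
#' correlates above the threshold; with a fixed seed the result is
#' deterministic.
#'
#' @param X Numeric training matrix.
#' @param threshold Absolute correlation above which a pair is redundant
#'   (default 0.9).
#' @param seed Integer seed for the scan order and the removal choice.
#' @return List with `kept` (column indices, increasing), `state`, and
#'   `transformed`.
#' @export
pcc_reduce <- function(X, threshold = 0.9, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop_input("need at least 2 rows")
  p <- ncol(X)
  if (p < 2L) {
    state <- list(kept = seq_len(p))
    return(list(kept = state$kept, state = state,
                transformed = X))
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0  # constant columns correlate with nothing
  pairs <- which(upper.tri(R), arr.ind = TRUE)
  alive <- rep(TRUE, p)
  with_seed(derive_seed(seed, "pcc"), {
    ord <- sample.int(nrow(pairs))
    for (r in ord) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (!alive[i] || !alive[j]) next
      if (abs(R[i, j]) > threshold) {
        victim <- if (stats::runif(1) < 0.5) i else j
        alive[victim] <- FALSE
      }
    }
  })
  kept <- which(alive)
  state <- list(kept = kept)
  list(kept = kept, state = state, transformed = X[, kept, drop = FALSE])
}

#' Principal component analysis reduction
#'
#' Components of the column-centered training matrix, ordered by
#' decreasing explained variance, with a deterministic sign convention
#' (the largest-magnitude loading of each component is positive).
#'
#' @param X Numeric training matrix.
#' @param n_components Number of components, at most `min(rows - 1, cols)`.
#' @return List with `state` (`center`, `loadings`, `explained_variance`)
#'   and `transformed` (scores).
#' @export
pca_reduce <- function(X, n_components) {
  X <- as.matrix(X)
  n_components <- as.integer(n_components)
  if (n_components > min(nrow(X) - 1L, ncol(X)))
    stop_input("n_components exceeds min(rows - 1, cols)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(n_components), drop = FALSE]
  for (k in seq_len(ncol(W))) {
    top <- which.max(abs(W[, k]))
    if (W[top, k] < 0) W[, k] <- -W[, k]
  }
  state <- list(center = pc$center, loadings = W,
                explained_variance = pc$sdev^2)
  list(state = state, transformed = apply_reducer_pca(state, X))
}

apply_reducer_pca <- function(state, X) {
  sweep(as.matrix(X), 2, state$center) %*% state$loadings
}
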