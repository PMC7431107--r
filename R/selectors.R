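# Stage 3: feature selection. Every selector returns features in
# decreasing order of merit together with the score the report prints
# (ANOVA F-values, Relief weights, RFE elimination rank).

#' Rank features by one-way ANOVA F-value
#'
#' For a binary outcome the two-group F statistic
#' `F = MS_between / MS_within` on `(1, n - 2)` degrees of freedom, which
#' equals the square of the pooled-variance two-sample t statistic.
#' Features identical in both classes get `F = 0`; a feature with zero
#' within-group variance but distinct group means gets `F = Inf` and ranks
#' first (logged). Ties keep column order.
#'
#' @param X Numeric matrix.
#' @param y Binary 0/1 vector.
#' @param log Optional log object.
#' @return Data frame `feature`, `score` (F), `column`, sorted by
#'   decreasing F.
#' @export
anova_rank <- function(X, y, log = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) != 2L) stop_input("both classes must be present")
  n <- length(y)
  g1 <- y == 1L
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(X[g1, , drop = FALSE])
  m0 <- colMeans(X[!g1, , drop = FALSE])
  grand <- colMeans(X)
  ss_b <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
  ss_w <- colSums(sweep(X[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(X[!g1, , drop = FALSE], 2, m0)^2)
  ms_b <- ss_b / 1
  ms_w <- ss_w / (n - 2)
  f <- ifelse(ms_w > 0, ms_b / ms_w, ifelse(ms_b > 0, Inf, 0))
  if (any(is.infinite(f)))
    log_line(log, "feature(s) with zero within-class variance ranked first: ",
             paste(colnames(X)[is.infinite(f)] %||% which(is.infinite(f)),
                   collapse = ", "))
  ord <- order(-f)  # stable: ties keep column order
  data.frame(feature = (colnames(X) %||% sprintf("V%d", seq_len(ncol(X))))[ord],
             score = f[ord], column = ord, row.names = NULL)
}

#' Rank features by the Relief weight
#'
#' Classic Relief: features are internally rescaled to `[0, 1]`; for each
#' sampled case the nearest same-class hit `H` and nearest other-class
#' miss `M` (Euclidean distance over all features) update each feature
#' weight by `|x - M| - |x - H|`, averaged over iterations. `k_neighbors`
#' greater than 1 averages over the k nearest hits and misses (the ReliefF
#' extension).
#'
#' @param X Numeric matrix.
#' @param y Binary 0/1 vector; each class needs at least 2 cases.
#' @param n_iterations Sampled cases; defaults to all cases, visited in
#'   order (no sampling noise).
#' @param k_neighbors Nearest hits/misses averaged per case (default 1).
#' @param seed Seed for the case sample when `n_iterations < n`.
#' @return Data frame `feature`, `score` (weight), `column`, sorted by
#'   decreasing weight; ties keep column order.
#' @export
relief_rank <- function(X, y, n_iterations = nrow(X), k_neighbors = 1L,
                        seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X); p <- ncol(X)
  if (min(table(factor(y, levels = 0:1))) < 2L)
    stop_input("each class needs at least 2 cases")
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # constant features contribute 0 everywhere
  Z <- sweep(sweep(X, 2, rng[1, ]), 2, span, `/`)
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  picks <- if (n_iterations >= n) seq_len(n) else
    with_seed(derive_seed(seed, "relief"), sample.int(n, n_iterations))
  w <- numeric(p)
  for (i in picks) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(diff))
    hits <- same[order(D[i, same])[seq_len(kh)]]
    misses <- diff[order(D[i, diff])[seq_len(km)]]
    dh <- colMeans(abs(Z[hits, , drop = FALSE] -
                         matrix(Z[i, ], kh, p, byrow = TRUE)))
    dm <- colMeans(abs(Z[misses, , drop = FALSE] -
                         matrix(Z[i, ], km, p, byrow = TRUE)))
    w <- w + dm - dh
  }
  w <- w / length(picks)
  ord <- order(-w)
  data.frame(feature = (colnames(X) %||% sprintf("V%d", seq_len(ncol(X))))[ord],
             score = w[ord], column = ord, row.names = NULL)
}

#' Rank features by recursive feature elimination
#'
#' Repeatedly fits a linear base estimator and drops the feature with the
#' smallest absolute coefficient until `n_features` remain. The score is
#' the elimination rank (survivors get the highest ranks); the full
#' elimination order is returned so any prefix is available.
#'
#' @param X Numeric matrix.
#' @param y Binary 0/1 vector.
#' @param n_features Number of survivors.
#' @param base One of `"lda"` (discriminant scaling coefficients) or
#'   `"logistic"` (GLM coefficients).
#' @return Data frame `feature`, `score` (elimination rank; larger =
#'   retained longer), `column`, survivors first in final-fit coefficient
#'   order, then eliminated features in reverse elimination order.
#' @export
rfe_rank <- function(X, y, n_features = 1L, base = c("lda", "logistic")) {
  base <- match.arg(base)
  X <- as.matrix(X)
  y <- as.integer(y)
  p <- ncol(X)
  if (n_features > p) stop_input("n_features exceeds available features")
  if (length(unique(y)) != 2L) stop_input("both classes must be present")
  cols <- seq_len(p)
  eliminated <- integer(0)
  while (length(cols) > n_features) {
    coefs <- linear_coefs(X[, cols, drop = FALSE], y, base)
    worst <- which.min(abs(coefs))
    eliminated <- c(eliminated, cols[worst])
    cols <- cols[-worst]
  }
  ord <- c(cols, rev(eliminated))
  # survivors share the top rank; eliminated features ranked by how long
  # they survived
  rank_score <- c(rep(p, length(cols)),
                  if (length(eliminated)) seq(p - length(cols), 1) else integer(0))
  data.frame(feature = (colnames(X) %||% sprintf("V%d", seq_len(p)))[ord],
             score = rank_score, column = ord, row.names = NULL)
}

# Per-feature coefficients of a linear model on standardized columns, so
# magnitudes are comparable across features.
linear_coefs <- function(X, y, base) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, `/`)
  if (base == "lda") {
    fit <- suppressWarnings(MASS::lda(Z, grouping = factor(y, levels = 0:1)))
    as.numeric(fit$scaling[, 1])
  } else {
    fit <- suppressWarnings(stats::glm.fit(cbind(1, Z), y,
                                           family = stats::binomial()))
    fit$coefficients[-1]
  }
}
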