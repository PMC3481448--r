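# High-level evaluation: per-protein t-tests, marker recovery, feature
# selection, KNN/LDA classification, and the binomial quantification bound.

#' Row-wise equal-variance two-sample t statistics
#'
#' For each row of `x`, computes `t = |m1 - m0| / sqrt((Var1 + Var0) / M)`
#' with class means `m` and unbiased class variances `Var` over the two
#' equal-size classes, and a two-sided p-value on 2M - 2 degrees of freedom.
#' Rows with zero pooled variance give t = 0 (equal means) or t = Inf
#' (different means, p = 0).
#'
#' @param x Numeric matrix (features x samples).
#' @param labels 0/1 class labels, one per column; classes must be equal
#'   sized.
#' @return A tibble with columns `statistic` and `p.value`, one row per
#'   feature.
#' @export
t_statistics <- function(x, labels) {
  labels <- as.integer(labels)
  i0 <- which(labels == 0L)
  i1 <- which(labels == 1L)
  M <- length(i0)
  if (M < 2L || length(i1) != M) {
    abort("classes must be equal sized with at least 2 samples each")
  }
  x0 <- x[, i0, drop = FALSE]
  x1 <- x[, i1, drop = FALSE]
  m0 <- rowMeans(x0)
  m1 <- rowMeans(x1)
  v0 <- rowSums((x0 - m0)^2) / (M - 1)
  v1 <- rowSums((x1 - m1)^2) / (M - 1)
  se <- sqrt((v0 + v1) / M)
  num <- abs(m1 - m0)
  stat <- ifelse(se > 0, num / se, ifelse(num > 0, Inf, 0))
  pv <- 2 * pt(stat, df = 2 * M - 2, lower.tail = FALSE)
  pv[is.infinite(stat)] <- 0
  tibble::tibble(statistic = stat, p.value = pv)
}

#' Fraction of true markers recovered by differential expression testing
#'
#' A marker counts as detected when its per-protein t-test on estimated
#' concentrations is significant at `alpha_level`. Markers that are all-zero
#' in both classes (never quantified) cannot be detected.
#'
#' @param estimate A `protein_estimate` (or concentration matrix).
#' @param labels 0/1 class labels per sample.
#' @param marker_idx Row indices of the true markers.
#' @param alpha_level Significance level.
#' @return Percentage (0-100) of markers detected.
#' @export
detect_markers <- function(estimate, labels, marker_idx,
                           alpha_level = 0.05) {
  if (length(marker_idx) == 0) abort("no markers supplied")
  x <- if (inherits(estimate, "protein_estimate")) {
    estimate$conc_hat
  } else {
    estimate
  }
  tt <- t_statistics(x, labels)
  100 * mean(tt$p.value[marker_idx] < alpha_level)
}

#' Select the top differentially expressed features
#'
#' Ranks features by |t| on the training data and keeps the `n_features`
#' largest; ties are broken toward the smaller row index. If fewer features
#' than requested are quantified (have any nonzero value), only the
#' quantified ones are returned, with a warning.
#'
#' @param x Training matrix (features x samples).
#' @param labels 0/1 training labels.
#' @param n_features Number of features to keep.
#' @return Integer vector of selected row indices, in rank order.
#' @export
select_features <- function(x, labels, n_features = 20) {
  check_count(n_features, "n_features", 1L)
  tt <- t_statistics(x, labels)
  ord <- order(-tt$statistic, seq_len(nrow(x)))
  quantified <- which(rowSums(x != 0) > 0)
  if (length(quantified) < n_features) {
    warn(sprintf("only %d of %d requested features are quantified",
                 length(quantified), n_features))
    return(ord[ord %in% quantified])
  }
  ord[seq_len(n_features)]
}

# K-nearest-neighbour prediction by exhaustive Euclidean distance; distance
# ties resolve toward the smaller training index (stable order()).
knn_predict <- function(train, labels, test, k = 3) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  d2 <- outer(rowSums(test^2), rep(1, nrow(train))) +
    outer(rep(1, nrow(test)), rowSums(train^2)) -
    2 * tcrossprod(test, train)
  apply(d2, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    as.integer(mean(labels[nn]) > 0.5)
  })
}

# Two-class LDA with pooled covariance, equal priors and a small ridge on the
# pooled covariance so constant or collinear features stay invertible.
lda_train_predict <- function(train, labels, test, ridge = 1e-6) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  x0 <- train[labels == 0L, , drop = FALSE]
  x1 <- train[labels == 1L, , drop = FALSE]
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  n0 <- nrow(x0)
  n1 <- nrow(x1)
  Sp <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) /
    (n0 + n1 - 2)
  Sp <- Sp + diag(ridge, ncol(train))
  w <- solve(Sp, m1 - m0)
  thresh <- sum(w * (m1 + m0)) / 2
  as.integer(test %*% w > thresh)
}

#' Train and test KNN and LDA classifiers
#'
#' KNN uses Euclidean distance with majority vote among `knn_k` neighbours
#' (distance ties resolve toward the smaller training index). LDA uses the
#' pooled within-class covariance with equal priors and a ridge of 1e-6 for
#' invertibility. Both are trained on the training matrix (samples x
#' selected features) and scored on an independent test matrix.
#'
#' @param train,test Numeric matrices, samples x features (same features).
#' @param train_labels,test_labels 0/1 labels.
#' @param knn_k Neighbour count.
#' @return A list with misclassification rates `err_knn` and `err_lda`.
#' @export
train_and_test_classifiers <- function(train, train_labels, test,
                                       test_labels, knn_k = 3) {
  check_count(knn_k, "knn_k", 1L)
  pred_knn <- knn_predict(train, train_labels, test, k = knn_k)
  pred_lda <- lda_train_predict(train, train_labels, test)
  list(err_knn = mean(pred_knn != test_labels),
       err_lda = mean(pred_lda != test_labels))
}

#' Binomial upper bound on the protein quantification probability
#'
#' If each of a protein's `n` peptides is identified independently with
#' probability `q`, the protein can be quantified only when at least two
#' peptides are identified, so the quantification probability is bounded by
#' `P(at least 2 successes) = 1 - (1-q)^n - n q (1-q)^(n-1)`. The roll-up
#' quality filters can only lower it, hence "upper bound".
#'
#' @param q Per-peptide identification probability in \[0, 1\].
#' @param n Peptides per protein, at least 2.
#' @return The bound, a probability.
#' @examples
#' quantification_upper_bound(0.17, 20)  # ~ 0.88
#' @export
quantification_upper_bound <- function(q, n) {
  check_scalar(q, "q", lower = 0, upper = 1)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    abort("`n` must be an integer >= 2")
  }
  1 - (1 - q)^n - n * q * (1 - q)^(n - 1)
}
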