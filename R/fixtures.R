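#' Two-class dataset whose discriminant direction has the smallest variance
#'
#' Constructs a Gaussian two-class dataset in which overall variance and
#' class separation are anti-aligned: the highest-variance axes carry little
#' or no class information while the lowest-variance axis carries the
#' largest mean separation. Plain PCA therefore ranks the discriminative
#' direction last, whereas the decreasing rule ranks it first. Per-axis
#' standard deviations are `sds` and per-axis class-mean offsets are
#' `+/- seps / 2`.
#'
#' @param n_per_class samples per class.
#' @param sds per-dimension standard deviations (decreasing).
#' @param seps per-dimension between-class mean separations (increasing).
#' @param seed integer seed.
#' @return list with `x` (matrix), `labels` (factor "a"/"b").
#' @export
simulate_discriminant_classes <- function(n_per_class = 100,
                                          sds = c(4.5, 2.5, 1.5, 0.6),
                                          seps = c(1.6, 2.4, 3, 3.6),
                                          seed = 1L) {
  stopifnot(length(sds) == length(seps))
  set.seed(seed)
  b <- length(sds)
  mk <- function(sign) {
    sweep(matrix(stats::rnorm(n_per_class * b), n_per_class, b) %*% diag(sds),
          2, sign * seps / 2, "+")
  }
  x <- rbind(mk(-1), mk(+1))
  labels <- factor(rep(c("a", "b"), each = n_per_class))
  idx <- sample(nrow(x))
  list(x = x[idx, , drop = FALSE], labels = labels[idx])
}

#' Hold-out accuracy of 1-NN on reduced projections
#'
#' Fits the reducer on a training split, projects both splits to `d`
#' dimensions and classifies the held-out half with 1-nearest-neighbor.
#' Used to compare the decreasing-rule ordering against plain PCA on
#' constructed fixtures.
#'
#' @param data list with `x`, `labels` (e.g. from
#'   [simulate_discriminant_classes()]).
#' @param method "drpca" or "pca".
#' @param d retained dimension.
#' @param train_frac fraction of rows used for fitting.
#' @param seed split seed.
#' @return hold-out accuracy in `[0, 1]`.
#' @export
reduced_knn_accuracy <- function(data, method, d, train_frac = 0.5, seed = 1L) {
  set.seed(seed)
  n <- nrow(data$x)
  tr <- sample(n, round(train_frac * n))
  red <- fit_reducer(data$x[tr, , drop = FALSE], data$labels[tr],
                     method = method, d = d)
  ptr <- project_samples(red$ranking, data$x[tr, , drop = FALSE], d)
  pte <- project_samples(red$ranking, data$x[-tr, , drop = FALSE], d)
  pred <- class::knn(ptr, pte, data$labels[tr], k = 1)
  mean(pred == data$labels[-tr])
}
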