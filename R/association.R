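#' Z-score normalization
#'
#' `y = (x - mean(x)) / sd(x)` with the population standard deviation
#' (divide by n) by default, so the output has mean 0 and unit population
#' standard deviation.
#'
#' @param x numeric vector.
#' @param population use the population (divide-by-n) sd; set FALSE for the
#'   sample (n-1) convention.
#' @param name label used in the zero-variance error message.
#' @return normalized vector with attributes `center` and `scale`.
#' @export
zscore <- function(x, population = TRUE, name = deparse(substitute(x))) {
  m <- mean(x)
  s <- if (population) sqrt(mean((x - m)^2)) else stats::sd(x)
  if (is.na(s) || s == 0)
    stop("zscore: '", name, "' has zero standard deviation", call. = FALSE)
  y <- (x - m) / s
  attr(y, "center") <- m
  attr(y, "scale") <- s
  y
}

#' Matrix-form Pearson correlation of features with glucose
#'
#' Centers the n x m feature matrix and the glucose vector, forms the
#' cross-covariance `Sxy = Xc^T Gc / (n-1)` and the self-covariances, and
#' returns `r = Sxy / sqrt(Sxx Syy)` per feature with two-sided p-values
#' from the exact t transform `t = r sqrt(n-2) / sqrt(1-r^2)`.
#'
#' @param X n x m feature matrix.
#' @param G length-n glucose vector, mmol/L.
#' @return data.frame with columns `feature`, `r`, `p`; constant feature
#'   columns get `NA` with a warning.
#' @export
pearson_features_vs_glucose <- function(X, G) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (length(G) != n) stop("X and G sizes differ", call. = FALSE)
  gc <- G - mean(G)
  syy <- sum(gc^2) / (n - 1)
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2) / (n - 1)
  sxy <- drop(crossprod(xc, gc)) / (n - 1)
  r <- rep(NA_real_, ncol(X))
  ok <- sxx > 0 & syy > 0
  if (any(!ok)) warning("constant feature column: correlation undefined",
                        call. = FALSE)
  r[ok] <- sxy[ok] / sqrt(sxx[ok] * syy)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("feature", seq_len(ncol(X)))
  data.frame(feature = nm, r = r, p = p, row.names = NULL)
}

#' Pooled-window association analysis
#'
#' Pools the windows of all subjects and both states and correlates each of
#' the ten features with the reference glucose values.
#'
#' @param features data.frame from [feature_table()].
#' @return data.frame with `feature`, `r`, `p` (one row per lambda feature).
#' @export
association_table <- function(features) {
  X <- as.matrix(features[, feature_names()])
  pearson_features_vs_glucose(X, features$glucose_mmol_per_l)
}
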