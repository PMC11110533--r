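# Independent brute-force oracles used across the suite. Each is written
# directly from the defining formulas, element by element, deliberately
# avoiding the package's vectorized/matrix code paths.

oracle_features <- function(x, dt) {
  T <- length(x)
  m <- 0; for (v in x) m <- m + v; m <- m / T
  ss <- 0; for (v in x) ss <- ss + (v - m)^2
  d1 <- numeric(T - 1)
  for (i in 2:T) d1[i - 1] <- x[i] - x[i - 1]
  m1 <- sum(d1) / (T - 1)
  s1 <- sqrt(sum((d1 - m1)^2) / (T - 1))
  d2 <- numeric(T - 2)
  for (i in 3:T) d2[i - 2] <- x[i] - 2 * x[i - 1] + x[i - 2]
  m2 <- sum(d2) / (T - 2)
  s2 <- sqrt(sum((d2 - m2)^2) / (T - 2))
  e <- 0; ee <- 0
  for (v in x) {
    e <- e + v^2 * dt
    if (v^2 > 0) ee <- ee - v^2 * log(v^2) * dt
  }
  c(lambda1 = m, lambda2 = sqrt(ss / T), lambda3 = m1, lambda4 = s1,
    lambda5 = m2, lambda6 = s2, lambda7 = max(x), lambda8 = max(x) - min(x),
    lambda9 = e, lambda10 = ee)
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p_one = pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

oracle_zscore <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / length(x))
  (x - m) / s
}

oracle_cbsi <- function(hbo, hbr) {
  alpha <- sqrt(sum((hbo - mean(hbo))^2) / (length(hbo) - 1)) /
    sqrt(sum((hbr - mean(hbr))^2) / (length(hbr) - 1))
  hbo2 <- (hbo - alpha * hbr) / 2
  list(dhbo = hbo2, dhbr = -hbo2 / alpha, alpha = alpha)
}

oracle_metrics <- function(yhat, y) {
  n <- length(y)
  rmse <- 0; mard <- 0
  for (i in seq_len(n)) {
    rmse <- rmse + (yhat[i] - y[i])^2
    mard <- mard + abs(yhat[i] - y[i]) / y[i]
  }
  list(rmse = sqrt(rmse / n), mard_percent = 100 * mard / n)
}

oracle_scatter <- function(x, labels) {
  b <- ncol(x)
  grand <- colMeans(x)
  within <- matrix(0, b, b); between <- matrix(0, b, b)
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    for (j in seq_len(nrow(xi)))
      within <- within + outer(xi[j, ] - mi, xi[j, ] - mi)
    between <- between + nrow(xi) * outer(mi - grand, mi - grand)
  }
  list(within = within, between = between)
}

oracle_xi_order <- function(vectors, between, within, ridge) {
  xi <- numeric(ncol(vectors))
  for (k in seq_len(ncol(vectors))) {
    ck <- vectors[, k]
    xi[k] <- sum(ck * (between %*% ck)) / (sum(ck * (within %*% ck)) + ridge)
  }
  xi
}

oracle_od <- function(intensity) {
  ref <- sum(intensity) / length(intensity)
  vapply(intensity, function(v) -log10(v / ref), 0)
}

# amplitude of a sinusoidal component at frequency f, ignoring filter edges
measure_amplitude <- function(x, core_frac = 0.5) {
  n <- length(x)
  lo <- round(n * (1 - core_frac) / 2)
  max(abs(x[lo:(n - lo)]))
}
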