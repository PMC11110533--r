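#' Principal component decomposition of a training matrix
#'
#' Eigendecomposition of the centered scatter matrix
#' `Pi = sum_k (x_k - xbar)(x_k - xbar)^T`. Eigenvalues are non-negative and
#' sorted descending; eigenvectors are unit-norm and mutually orthogonal,
#' with the sign convention that each vector's largest-magnitude entry is
#' positive.
#'
#' @param gamma a x b training matrix (a samples, b features).
#' @return list with `vectors` (b x b), `values` (length b), `center`
#'   (training mean), `scatter` (Pi), and `zero_variance` flag.
#' @export
fit_pca <- function(gamma) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) < 2) stop("need at least 2 training samples", call. = FALSE)
  center <- colMeans(gamma)
  xc <- sweep(gamma, 2, center)
  scatter <- crossprod(xc)
  eg <- eigen(scatter, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  vectors <- apply(eg$vectors, 2, fix_sign)
  list(vectors = vectors, values = values, center = center,
       scatter = scatter, zero_variance = all(values < 1e-12))
}

fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

#' Within- and between-class scatter matrices
#'
#' `Pi_ICS = sum_i sum_j (x_ij - xbar_i)(x_ij - xbar_i)^T` over classes i and
#' their samples, and `Pi_IS = sum_i a_i (K_i - Kbar)(K_i - Kbar)^T` with
#' class sizes a_i, class means K_i and grand mean Kbar. Their sum equals the
#' total scatter about the grand mean.
#'
#' @param gamma a x b data matrix.
#' @param labels class label per row.
#' @return list with `within` (Pi_ICS), `between` (Pi_IS), `total`.
#' @export
compute_scatter <- function(gamma, labels) {
  gamma <- as.matrix(gamma)
  labels <- as.character(labels)
  stopifnot(nrow(gamma) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2)
    warning("single class: between-class scatter is zero", call. = FALSE)
  b <- ncol(gamma)
  grand <- colMeans(gamma)
  within <- matrix(0, b, b)
  between <- matrix(0, b, b)
  for (cl in classes) {
    xi <- gamma[labels == cl, , drop = FALSE]
    mi <- colMeans(xi)
    xc <- sweep(xi, 2, mi)
    within <- within + crossprod(xc)
    dm <- mi - grand
    between <- between + nrow(xi) * tcrossprod(dm)
  }
  total <- crossprod(sweep(gamma, 2, grand))
  list(within = within, between = between, total = total)
}

#' Rank PCA eigenvectors by class-discrimination score (decreasing rule)
#'
#' Scores every eigenvector `C_k` with the Fisher-style ratio
#' `xi(C_k) = (C_k^T Pi_IS C_k) / (C_k^T Pi_ICS C_k + ridge)` and reorders
#' the basis by non-increasing xi. Ties (including the degenerate case
#' `Pi_IS = 0`, where all xi are 0) are broken by descending eigenvalue and
#' then by original index, so the degenerate ordering falls back to plain
#' PCA order.
#'
#' @param pca output of [fit_pca()].
#' @param scatter output of [compute_scatter()].
#' @param ridge denominator regularizer; default
#'   `1e-12 * trace(Pi_ICS) / b`.
#' @return list of class `drpca_ranking`: `vectors` (reordered basis),
#'   `values` (matching eigenvalues), `xi` (non-increasing scores), `order`
#'   (permutation of the PCA order), `center`.
#' @export
rank_eigenvectors <- function(pca, scatter, ridge = NULL) {
  v <- pca$vectors
  b <- ncol(v)
  if (is.null(ridge)) ridge <- 1e-12 * sum(diag(scatter$within)) / b
  xi <- vapply(seq_len(b), function(k) {
    ck <- v[, k]
    num <- drop(crossprod(ck, scatter$between %*% ck))
    den <- drop(crossprod(ck, scatter$within %*% ck)) + ridge
    num / den
  }, 0)
  ord <- order(-xi, -pca$values, seq_len(b))
  structure(list(vectors = v[, ord, drop = FALSE],
                 values = pca$values[ord],
                 xi = xi[ord],
                 order = ord,
                 center = pca$center),
            class = "drpca_ranking")
}

#' Choose the retained projection dimension
#'
#' Either an explicit `d`, or the smallest `d` whose cumulative normalized
#' score reaches `threshold` ("contribution" mode; scores are the xi values
#' for a decreasing-rule ranking, eigenvalues for plain PCA).
#'
#' @param scores non-negative importance scores in ranked order.
#' @param mode "explicit" or "contribution".
#' @param d explicit dimension (mode "explicit").
#' @param threshold cumulative-contribution threshold in (0, 1], default 0.9.
#' @return integer dimension.
#' @export
select_components <- function(scores, mode = c("contribution", "explicit"),
                              d = NULL, threshold = 0.9) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(d) || d < 1 || d > length(scores))
      stop("explicit d must lie in 1..", length(scores), call. = FALSE)
    return(as.integer(d))
  }
  if (threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  tot <- sum(scores)
  if (tot <= 0) return(1L)
  cum <- cumsum(scores) / tot
  if (threshold == 1) return(as.integer(sum(scores > 0)))
  as.integer(which(cum >= threshold)[1])
}

#' Project samples onto a ranked basis
#'
#' Samples are centered by the *training* mean and projected onto the first
#' `d` ranked eigenvectors.
#'
#' @param ranking a `drpca_ranking` (or the list from [fit_pca()] with the
#'   same fields).
#' @param samples matrix of rows to project (dimension must equal the
#'   training feature dimension).
#' @param d retained dimension.
#' @return n x d matrix of projections.
#' @export
project_samples <- function(ranking, samples, d = ncol(ranking$vectors)) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(ranking$center))
    stop("sample dimension does not match training dimension", call. = FALSE)
  if (d > ncol(ranking$vectors)) stop("d exceeds available vectors", call. = FALSE)
  xc <- sweep(samples, 2, ranking$center)
  xc %*% ranking$vectors[, seq_len(d), drop = FALSE]
}

#' Fit a (DR-)PCA reducer
#'
#' Convenience wrapper: plain PCA keeps eigenvalue order; the decreasing
#' rule re-ranks the eigenvectors by the between/within-class scatter ratio
#' computed from `labels`.
#'
#' @param x training matrix.
#' @param labels class labels (required for `method = "drpca"`).
#' @param method "drpca" or "pca".
#' @param d explicit dimension, or NULL to use the cumulative-contribution
#'   rule at `threshold`.
#' @param threshold contribution threshold, default 0.9.
#' @return list of class `fnirs_reducer` with the ranked basis, scores,
#'   retained `d`, `method` and training mean.
#' @export
fit_reducer <- function(x, labels = NULL, method = c("drpca", "pca"),
                        d = NULL, threshold = 0.9) {
  method <- match.arg(method)
  pca <- fit_pca(x)
  if (method == "drpca") {
    if (is.null(labels)) stop("drpca needs class labels", call. = FALSE)
    sc <- compute_scatter(x, labels)
    ranking <- rank_eigenvectors(pca, sc)
    scores <- ranking$xi
  } else {
    ranking <- structure(list(vectors = pca$vectors, values = pca$values,
                              xi = NULL, order = seq_along(pca$values),
                              center = pca$center),
                         class = "drpca_ranking")
    scores <- pca$values
  }
  dd <- if (is.null(d))
    select_components(scores, "contribution", threshold = threshold)
  else
    select_components(scores, "explicit", d = d)
  structure(list(ranking = ranking, scores = scores, d = dd,
                 method = method, center = pca$center),
            class = "fnirs_reducer")
}

#' Serialize / restore a fitted reducer
#'
#' @param reducer an `fnirs_reducer`.
#' @param path JSON file path.
#' @return `reducer_to_json` writes and returns the path invisibly;
#'   `reducer_from_json` returns the restored reducer.
#' @export
reducer_to_json <- function(reducer, path) {
  obj <- list(method = reducer$method, d = reducer$d,
              center = reducer$center,
              vectors = reducer$ranking$vectors,
              values = reducer$ranking$values,
              xi = reducer$ranking$xi,
              scores = reducer$scores)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname reducer_to_json
#' @export
reducer_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ranking <- structure(list(vectors = as.matrix(obj$vectors),
                            values = obj$values, xi = obj$xi,
                            order = NULL, center = obj$center),
                       class = "drpca_ranking")
  structure(list(ranking = ranking, scores = obj$scores, d = as.integer(obj$d),
                 method = obj$method, center = obj$center),
            class = "fnirs_reducer")
}
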