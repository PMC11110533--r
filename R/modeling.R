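#' Leave-one-subject-out folds
#'
#' @param subject_ids vector of unique subject identifiers.
#' @return list of folds, each `list(train = ids, test = id)`; one fold per
#'   subject.
#' @export
loso_split <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) stop("duplicate subject ids", call. = FALSE)
  if (length(subject_ids) < 2) stop("need at least 2 subjects", call. = FALSE)
  lapply(subject_ids, function(s)
    list(train = subject_ids[subject_ids != s], test = s))
}

#' Prediction metrics
#'
#' Regression: `RMSE = sqrt(mean((yhat-y)^2))`, `MARD = 100 mean(|yhat-y|/y)`
#' (percent; requires y > 0), and Pearson r between predictions and
#' references. Classification: percent of correctly predicted labels.
#'
#' @param yhat predictions (numeric, or labels for classification).
#' @param y references.
#' @param task "regression" or "classification".
#' @return named list of metrics.
#' @export
compute_metrics <- function(yhat, y, task = c("regression", "classification")) {
  task <- match.arg(task)
  if (length(yhat) != length(y)) stop("length mismatch", call. = FALSE)
  if (task == "classification") {
    return(list(accuracy_percent = 100 * mean(as.character(yhat) == as.character(y))))
  }
  if (any(y <= 0)) stop("MARD needs positive reference values", call. = FALSE)
  err <- yhat - y
  r <- if (stats::sd(yhat) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(yhat, y)
  list(rmse = sqrt(mean(err^2)),
       mard_percent = 100 * mean(abs(err) / y),
       pearson_r = r)
}

## ---- model backends -------------------------------------------------------

model_grids <- function() {
  list(knn = list(k = c(1, 3, 5, 7, 9)),
       rf = list(ntree = c(100, 300)),
       svm = list(cost = c(0.1, 1, 10)),
       xgb = list(max_depth = c(2, 3)))
}

fit_model <- function(model, hyper, x, y, task, seed = 1L) {
  x <- as.matrix(x)
  if (task == "classification") y <- factor(y)
  set.seed(seed)
  switch(model,
    knn = {
      k <- min(hyper, nrow(x))         # cannot use more neighbors than rows
      if (task == "regression")
        list(kind = "knnreg", fit = caret::knnreg(x, y, k = k),
             x = x, y = y, k = k)
      else
        list(kind = "knnclass", x = x, y = y, k = k)
    },
    rf = list(kind = "rf",
              fit = randomForest::randomForest(x, y, ntree = hyper)),
    svm = list(kind = "svm",
               fit = e1071::svm(x, y, cost = hyper, kernel = "radial")),
    xgb = {
      yy <- if (task == "classification") as.numeric(y) - 1 else y
      obj <- if (task == "classification") "binary:logistic" else "reg:squarederror"
      dtrain <- xgboost::xgb.DMatrix(x, label = yy, nthread = 1)
      list(kind = "xgb", levels = levels(y),
           fit = xgboost::xgb.train(
             params = list(objective = obj, max_depth = hyper, eta = 0.3,
                           nthread = 1),
             data = dtrain, nrounds = 50, verbose = 0))
    },
    stop("unknown model '", model, "'", call. = FALSE))
}

predict_model <- function(fit, x, task) {
  x <- as.matrix(x)
  switch(fit$kind,
    knnreg = stats::predict(fit$fit, as.data.frame(x)),
    knnclass = as.character(class::knn(fit$x, x, fit$y, k = fit$k)),
    rf = {
      p <- stats::predict(fit$fit, x)
      if (task == "classification") as.character(p) else as.numeric(p)
    },
    svm = {
      p <- stats::predict(fit$fit, x)
      if (task == "classification") as.character(p) else as.numeric(p)
    },
    xgb = {
      p <- stats::predict(fit$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      if (task == "classification") fit$levels[(p > 0.5) + 1] else p
    })
}

## inner LOSO over training subjects to choose one hyperparameter value
tune_hyper <- function(model, x, y, subjects, task, grid, seed) {
  vals <- grid[[1]]
  if (length(vals) == 1) return(vals)
  uniq <- unique(subjects)
  if (length(uniq) < 2) return(vals[1])
  score <- vapply(vals, function(h) {
    errs <- vapply(uniq, function(s) {
      tr <- subjects != s
      if (task == "classification" && length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_model(model, h, x[tr, , drop = FALSE], y[tr], task, seed)
      p <- predict_model(fit, x[!tr, , drop = FALSE], task)
      if (task == "regression") sqrt(mean((p - y[!tr])^2))
      else mean(as.character(p) != as.character(y[!tr]))
    }, 0)
    mean(errs, na.rm = TRUE)
  }, 0)
  vals[which.min(score)]
}

#' Fit and predict one outer LOSO fold
#'
#' Training-fold feature columns are z-scored with training statistics, a
#' reducer (DR-PCA or plain PCA) is fitted on the training fold only, both
#' partitions are projected, the model hyperparameter is chosen by an inner
#' leave-one-subject-out loop over the training subjects, and predictions
#' are returned for the held-out subject. No held-out information enters any
#' training artifact.
#'
#' @param train,test data.frames with `subject_id`, `state`, the lambda
#'   feature columns and `glucose_mmol_per_l`.
#' @param reducer "drpca" or "pca".
#' @param model "knn", "rf", "svm" or "xgb".
#' @param d retained projection dimension.
#' @param task "regression" (glucose) or "classification" (state).
#' @param seed integer seed for stochastic backends.
#' @return list with `predictions`, `reference`, `hyper` (chosen value),
#'   `reducer_fit`.
#' @export
fit_predict_fold <- function(train, test, reducer = "drpca", model = "knn",
                             d = NULL, task = "regression", seed = 1L) {
  if (any(test$subject_id %in% train$subject_id))
    stop("leakage: held-out subject present in training fold", call. = FALSE)
  fn <- feature_names()
  xtr <- as.matrix(train[, fn])
  xte <- as.matrix(test[, fn])
  mu <- colMeans(xtr)
  sdev <- apply(xtr, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xtr <- sweep(sweep(xtr, 2, mu), 2, sdev, "/")
  xte <- sweep(sweep(xte, 2, mu), 2, sdev, "/")
  red <- fit_reducer(xtr, labels = train$state, method = reducer, d = d)
  ptr <- project_samples(red$ranking, xtr, red$d)
  pte <- project_samples(red$ranking, xte, red$d)
  y <- if (task == "regression") train$glucose_mmol_per_l else train$state
  grid <- model_grids()[[model]]
  hyper <- tune_hyper(model, ptr, y, train$subject_id, task, grid, seed)
  fit <- fit_model(model, hyper, ptr, y, task, seed)
  pred <- predict_model(fit, pte, task)
  ref <- if (task == "regression") test$glucose_mmol_per_l else test$state
  list(predictions = pred, reference = ref, hyper = hyper, reducer_fit = red)
}

#' Nested leave-one-subject-out evaluation
#'
#' Runs the outer LOSO loop for every combination of reducer, model and
#' projection dimension, pooling out-of-fold predictions for the metrics.
#' A missing model backend skips that cell with a warning.
#'
#' @param features feature table from [feature_table()] (all subjects).
#' @param reducers character subset of c("drpca", "pca").
#' @param models character subset of c("knn", "rf", "svm", "xgb").
#' @param d_values integer projection dimensions to evaluate.
#' @param task "regression" or "classification"; "both" evaluates the
#'   glucose regression and the state classification.
#' @param seed integer seed.
#' @return list with `results` (one row per cell and task: reducer, model,
#'   d, task, metrics, mean chosen hyperparameter) and `folds` (per-cell
#'   pooled predictions data.frame).
#' @export
run_evaluation <- function(features, reducers = c("drpca", "pca"),
                           models = "knn", d_values = 1:6,
                           task = "both", seed = 1L) {
  tasks <- if (task == "both") c("regression", "classification") else task
  folds <- loso_split(unique(features$subject_id))
  results <- list(); fold_preds <- list()
  d_values <- d_values[d_values <= length(feature_names())]
  for (red in reducers) for (mod in models) for (dd in d_values) for (tk in tasks) {
    cell <- sprintf("%s_%s_d%d_%s", red, mod, dd, tk)
    out <- tryCatch({
      preds <- list()
      for (f in folds) {
        tr <- features[features$subject_id %in% f$train, ]
        te <- features[features$subject_id == f$test, ]
        fp <- fit_predict_fold(tr, te, red, mod, dd, tk,
                               seed = seed + f$test)
        preds[[length(preds) + 1]] <- data.frame(
          subject_id = f$test,
          prediction = fp$predictions, reference = fp$reference,
          hyper = fp$hyper, stringsAsFactors = FALSE)
      }
      do.call(rbind, preds)
    }, error = function(e) {
      warning("cell ", cell, " skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(out)) next
    m <- if (tk == "regression")
      compute_metrics(as.numeric(out$prediction), as.numeric(out$reference),
                      "regression")
    else compute_metrics(out$prediction, out$reference, "classification")
    row <- data.frame(reducer = red, model = mod, d = dd, task = tk,
                      rmse = m$rmse %||% NA_real_,
                      mard_percent = m$mard_percent %||% NA_real_,
                      pearson_r = m$pearson_r %||% NA_real_,
                      accuracy_percent = m$accuracy_percent %||% NA_real_,
                      mean_hyper = mean(as.numeric(out$hyper)))
    results[[cell]] <- row
    fold_preds[[cell]] <- out
  }
  list(results = do.call(rbind, c(results, make.row.names = FALSE)),
       folds = fold_preds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict-training-mean baseline under LOSO
#'
#' For every fold, predicts the mean training-fold glucose for all held-out
#' windows; returns pooled metrics. This is the no-information reference any
#' useful predictor must beat.
#'
#' @param features feature table.
#' @return metrics list from [compute_metrics()].
#' @export
baseline_metrics <- function(features) {
  folds <- loso_split(unique(features$subject_id))
  preds <- unlist(lapply(folds, function(f) {
    tr <- features$glucose_mmol_per_l[features$subject_id %in% f$train]
    rep(mean(tr), sum(features$subject_id == f$test))
  }))
  refs <- unlist(lapply(folds, function(f)
    features$glucose_mmol_per_l[features$subject_id == f$test]))
  compute_metrics(preds, refs, "regression")
}
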