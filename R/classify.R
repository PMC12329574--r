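#' Hyperparameter grid for the gradient-boosted classifier
#'
#' The full baseline grid enumerates every combination of the five tuned
#' hyperparameters (4 x 8 x 5 x 6 x 6 = 5760 configurations) in
#' deterministic lexicographic order, the last argument varying fastest.
#'
#' @param colsample_bytree Feature subsample proportions per tree.
#' @param gamma Minimum loss reductions required to split.
#' @param learning_rate Shrinkage rates.
#' @param max_depth Maximum tree depths.
#' @param n_estimators Numbers of boosting rounds.
#' @return Data frame with one row per configuration, class `hyper_grid`.
#' @export
hyper_grid <- function(colsample_bytree = c(0.1, 0.3, 0.5, 0.7),
                       gamma = 0:7,
                       learning_rate = c(0.01, 0.04, 0.07, 0.1, 0.13),
                       max_depth = 1:6,
                       n_estimators = c(50, 100, 150, 200, 250, 300)) {
  stopifnot(length(colsample_bytree) > 0, length(gamma) > 0,
            length(learning_rate) > 0, length(max_depth) > 0,
            length(n_estimators) > 0)
  g <- expand.grid(n_estimators = n_estimators, max_depth = max_depth,
                   learning_rate = learning_rate, gamma = gamma,
                   colsample_bytree = colsample_bytree,
                   KEEP.OUT.ATTRS = FALSE)
  # lexicographic in the declared argument order, last varying fastest
  g <- g[, c("colsample_bytree", "gamma", "learning_rate", "max_depth",
             "n_estimators")]
  g <- g[do.call(order, g), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("hyper_grid", "data.frame")
  g
}

#' Reduced hyperparameter grid for desk-scale runs
#'
#' An 8-configuration subset of the full grid (values drawn from the
#' same tested lists) used by the simulation studies and the analysis
#' drivers, where re-running all 5760 configurations per replicate is
#' unnecessary.
#'
#' @return A `hyper_grid` with 8 rows.
#' @export
reduced_grid <- function() {
  hyper_grid(colsample_bytree = c(0.3, 0.7), gamma = 0,
             learning_rate = c(0.07, 0.13), max_depth = c(2, 4),
             n_estimators = 50)
}

#' Stratified k-fold split
#'
#' Partitions row indices into `k` disjoint folds such that each fold's
#' per-class counts differ by at most one from exact proportionality.
#' For the default design (100 rows, 4 classes of 25, k = 5) every fold
#' holds exactly 5 rows of each class.
#'
#' @param labels Class label per row (any type).
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds give identical folds.
#' @return List of `k` integer index vectors.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("every class must have at least k members for stratification")
  }
  set.seed(seed)
  folds <- vector("list", k)
  start <- 0L  # rotate remainder assignment across classes
  for (cl in names(counts)) {
    idx <- sample(which(labels == cl))
    assign <- ((seq_along(idx) - 1L + start) %% k) + 1L
    for (f in seq_len(k)) {
      folds[[f]] <- c(folds[[f]], idx[assign == f])
    }
    start <- (start + length(idx)) %% k
  }
  lapply(folds, sort)
}

# --- gradient-boosting backend -----------------------------------------
# The boosting learner itself is delegated to xgboost; the contract is a
# function taking train/test matrices, integer labels, one hyper_grid row
# and a seed, returning predicted integer labels for the test rows.

xgb_params <- function(config, n_classes, seed) {
  obj <- if (n_classes > 2L) {
    list(objective = "multi:softmax", num_class = n_classes)
  } else {
    list(objective = "binary:logistic")
  }
  c(obj, list(colsample_bytree = config$colsample_bytree,
              gamma = config$gamma, eta = config$learning_rate,
              max_depth = config$max_depth, nthread = 1L,
              seed = as.integer(seed)))
}

xgb_fit <- function(X, y, config, n_classes, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = xgb_params(config, n_classes, seed),
                     data = dtrain, nrounds = config$n_estimators,
                     verbose = 0)
}

xgb_predict_label <- function(booster, X, n_classes) {
  p <- predict(booster, xgboost::xgb.DMatrix(X))
  if (n_classes > 2L) as.integer(p) else as.integer(p > 0.5)
}

#' Default gradient-boosting backend
#'
#' Returns the backend function used by [grid_search()] and friends: an
#' xgboost fit-and-predict closure honoring the five tuned
#' hyperparameters plus a seed.
#'
#' @return A function
#'   `(X_train, y_train, X_test, config, n_classes, seed) -> integer labels`.
#' @export
xgb_backend <- function() {
  function(X_train, y_train, X_test, config, n_classes, seed) {
    booster <- xgb_fit(X_train, y_train, config, n_classes, seed)
    xgb_predict_label(booster, X_test, n_classes)
  }
}

#' Train one model on the full feature matrix
#'
#' @param fm A [feature_matrix()] (or one restricted via
#'   [subset_parcels()]).
#' @param config A single-row `hyper_grid` configuration.
#' @param seed Integer seed.
#' @return A `vocattn_model`: the fitted booster plus metadata.
#' @export
train_model <- function(fm, config, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), nrow(config) == 1L)
  n_classes <- length(unique(fm$labels))
  booster <- xgb_fit(fm$values, fm$labels, config, n_classes, seed)
  structure(list(booster = booster, config = config, n_classes = n_classes,
                 parcel_ids = fm$parcel_ids, seed = seed),
            class = "vocattn_model")
}

#' Cross-validated accuracy of one configuration
#'
#' Evaluates a configuration on fixed folds; each fold is held out once
#' while the model trains on the remainder.
#'
#' @param fm A [feature_matrix()].
#' @param config Single-row `hyper_grid` configuration.
#' @param folds Folds from [stratified_folds()].
#' @param seed Integer seed passed to the backend.
#' @param backend Backend function; see [xgb_backend()].
#' @return A `cv_result`: fold accuracies, their mean, and out-of-fold
#'   predictions aligned to rows.
#' @export
cv_config <- function(fm, config, folds, seed = 1L, backend = xgb_backend()) {
  stopifnot(inherits(fm, "feature_matrix"))
  n_classes <- length(unique(fm$labels))
  preds <- rep(NA_integer_, nrow(fm$values))
  fold_acc <- numeric(length(folds))
  for (f in seq_along(folds)) {
    te <- folds[[f]]
    tr <- setdiff(seq_len(nrow(fm$values)), te)
    yhat <- backend(fm$values[tr, , drop = FALSE], fm$labels[tr],
                    fm$values[te, , drop = FALSE], config, n_classes, seed)
    preds[te] <- yhat
    fold_acc[f] <- mean(yhat == fm$labels[te])
  }
  structure(list(config = config, fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc), predictions = preds,
                 n = nrow(fm$values)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean accuracy %.3f over %d folds (n = %d)\n",
              x$mean_accuracy, length(x$fold_accuracies), x$n))
  invisible(x)
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates every configuration of the grid on identical stratified
#' folds and returns the configuration with the highest mean validation
#' accuracy; ties are broken by grid order (first wins). A backend
#' failure on one configuration is recorded as a failed row and the
#' search continues; if all configurations fail, an error is raised.
#'
#' @param fm A [feature_matrix()].
#' @param grid A [hyper_grid()].
#' @param k Number of stratified folds.
#' @param seed Integer seed controlling both the folds and the backend.
#' @param backend Backend function; see [xgb_backend()].
#' @return A `grid_search_result` with elements `best` (a `cv_result`),
#'   `results` (one row per configuration with its mean and per-fold
#'   accuracies), and `folds`.
#' @export
grid_search <- function(fm, grid, k = 5L, seed = 1L, backend = xgb_backend()) {
  stopifnot(inherits(fm, "feature_matrix"), nrow(grid) >= 1L)
  folds <- stratified_folds(fm$labels, k, seed)
  results <- grid
  results$mean_accuracy <- NA_real_
  results$failed <- FALSE
  fold_cols <- paste0("fold", seq_len(k))
  for (fc in fold_cols) results[[fc]] <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    cv <- tryCatch(
      cv_config(fm, grid[i, , drop = FALSE], folds, seed, backend),
      error = function(e) e)
    if (inherits(cv, "error")) {
      results$failed[i] <- TRUE
      next
    }
    results$mean_accuracy[i] <- cv$mean_accuracy
    results[i, fold_cols] <- cv$fold_accuracies
    if (is.null(best) || cv$mean_accuracy > best$mean_accuracy) best <- cv
  }
  if (is.null(best)) stop("all grid configurations failed")
  structure(list(best = best, results = results, folds = folds,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid_search_result: %d configurations, best mean accuracy %.3f\n",
              nrow(x$results), x$best$mean_accuracy))
  invisible(x)
}

#' Confusion matrix of predicted against actual labels
#'
#' @param predictions,labels Equal-length label vectors.
#' @param classes Full class set (defaults to 0:3, the four-condition
#'   encoding).
#' @return Square count matrix, rows = actual, columns = predicted.
#' @export
confusion <- function(predictions, labels, classes = 0:3) {
  stopifnot(length(predictions) == length(labels))
  if (!all(predictions %in% classes) || !all(labels %in% classes)) {
    stop("label outside the class set")
  }
  m <- table(actual = factor(labels, levels = classes),
             predicted = factor(predictions, levels = classes))
  unclass(m)
}
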