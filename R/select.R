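#' Per-sample Shapley attributions of a trained model
#'
#' Exact tree-SHAP feature contributions from the boosted-tree backend,
#' returned as an `n x classes x features` array (the model's bias
#' column is dropped). For binary models the class dimension has length
#' one and attributions are toward the positive class.
#'
#' @param model A `vocattn_model` from [train_model()].
#' @param fm The [feature_matrix()] to explain (columns must match the
#'   model's features).
#' @return Numeric array of attributions.
#' @export
shap_values <- function(model, fm) {
  stopifnot(inherits(model, "vocattn_model"), inherits(fm, "feature_matrix"))
  if (!identical(model$parcel_ids, fm$parcel_ids)) {
    stop("feature matrix columns do not match the model's features")
  }
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(fm$values),
                     predcontrib = TRUE)
  n <- nrow(fm$values)
  p <- ncol(fm$values)
  if (length(dim(contrib)) == 3L) {
    out <- contrib[, , seq_len(p), drop = FALSE]       # n x class x (p+1)
  } else {
    out <- array(contrib[, seq_len(p), drop = FALSE], c(n, 1L, p))
  }
  dimnames(out) <- list(NULL, NULL, colnames(fm$values))
  out
}

#' Shapley-value feature ranking
#'
#' Ranks features by their importance score: the mean absolute Shapley
#' attribution aggregated over samples and classes. A feature that is
#' constant across all rows receives score 0.
#'
#' @param model A `vocattn_model` from [train_model()].
#' @param fm The [feature_matrix()] the model was trained on.
#' @return A `shap_summary`: `ranking` (column indices sorted by
#'   descending score, ties broken by column order), `scores` (per
#'   feature, in column order), and `shap` (the raw attribution array).
#' @export
shap_rank <- function(model, fm) {
  sv <- shap_values(model, fm)
  scores <- apply(abs(sv), 3L, mean)
  ranking <- order(-scores, seq_along(scores))
  structure(list(ranking = ranking, scores = scores, shap = sv,
                 parcel_ids = fm$parcel_ids),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  top <- utils::head(x$ranking, 5L)
  cat(sprintf("shap_summary: %d features; top by mean |SHAP|: %s\n",
              length(x$scores),
              paste(names(x$scores)[top], collapse = ", ")))
  invisible(x)
}

#' Apply the patience-based stopping rule to an accuracy trace
#'
#' "Improvement" means strictly exceeding the running maximum (a plateau
#' counts as no improvement). The scan stops once `patience` consecutive
#' non-improvements have occurred; the chosen iteration is the latest one
#' that set the running maximum. If the trace ends without triggering the
#' rule, the latest running-maximum iteration is chosen.
#'
#' @param accuracies Numeric accuracy per iteration.
#' @param patience Consecutive non-improvements tolerated (>= 1).
#' @return List with `stop_iteration` (last iteration examined) and
#'   `peak_iteration` (iteration of the latest running maximum).
#' @export
apply_stopping_rule <- function(accuracies, patience = 5L) {
  stopifnot(length(accuracies) >= 1L, patience >= 1L)
  best <- -Inf
  peak <- 0L
  stall <- 0L
  for (i in seq_along(accuracies)) {
    if (accuracies[i] > best) {
      best <- accuracies[i]
      peak <- i
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) {
        return(list(stop_iteration = i, peak_iteration = peak))
      }
    }
  }
  list(stop_iteration = length(accuracies), peak_iteration = peak)
}

#' Iterative add-one feature selection over a Shapley ranking
#'
#' Iteration `i` trains the fixed configuration on the top-`i` ranked
#' features (identical folds throughout) and records the mean validation
#' accuracy. Selection stops under the patience rule of
#' [apply_stopping_rule()]; the chosen feature count is the count at the
#' latest running-maximum iteration, i.e. `peak_iteration + peak_offset`.
#'
#' `peak_offset` exists because the mapping between a peak *iteration*
#' and the *number of features* retained admits two conventions; the
#' default (0) keeps iteration i = i features. `peak_offset = 1` retains
#' one feature beyond the peak iteration.
#'
#' @param ranking Feature column indices in rank order (from
#'   [shap_rank()], or any permutation prefix).
#' @param fm The full [feature_matrix()].
#' @param config Fixed single-row `hyper_grid` configuration.
#' @param k Folds for cross-validation.
#' @param seed Integer seed (folds and backend).
#' @param patience Consecutive non-improvements tolerated.
#' @param peak_offset 0 (default) or 1; see above.
#' @param backend Backend function; see [xgb_backend()].
#' @return A `selection_trace`: per-iteration `trace` data frame
#'   (`iteration`, `n_features`, `accuracy`), `chosen_count`,
#'   `stop_iteration`, and `selected` (column indices of the chosen set).
#' @export
iterative_select <- function(ranking, fm, config, k = 5L, seed = 1L,
                             patience = 5L, peak_offset = 0L,
                             backend = xgb_backend()) {
  if (length(ranking) < 1L) stop("empty feature ranking")
  stopifnot(inherits(fm, "feature_matrix"), patience >= 1L,
            peak_offset %in% c(0L, 1L))
  folds <- stratified_folds(fm$labels, k, seed)
  acc <- numeric(0)
  best <- -Inf
  stall <- 0L
  for (i in seq_along(ranking)) {
    sub <- subset_parcels(fm, ranking[seq_len(i)])
    cv <- cv_config(sub, config, folds, seed, backend)
    acc[i] <- cv$mean_accuracy
    if (acc[i] > best) {
      best <- acc[i]
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  rule <- apply_stopping_rule(acc, patience)
  chosen <- min(rule$peak_iteration + peak_offset, length(ranking))
  structure(list(
    trace = data.frame(iteration = seq_along(acc),
                       n_features = seq_along(acc), accuracy = acc),
    chosen_count = chosen, stop_iteration = rule$stop_iteration,
    selected = ranking[seq_len(chosen)], patience = as.integer(patience),
    peak_offset = as.integer(peak_offset)),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf(
    "selection_trace: stopped at iteration %d, chose %d feature(s), peak accuracy %.3f\n",
    x$stop_iteration, x$chosen_count, max(x$trace$accuracy)))
  invisible(x)
}

#' Re-search hyperparameters on the selected feature set
#'
#' Runs [grid_search()] restricted to the selected columns; with
#' `selected` covering all features this reduces exactly to the baseline
#' search.
#'
#' @param fm The full [feature_matrix()].
#' @param selected Column indices of the selected features.
#' @param grid A [hyper_grid()].
#' @param k Folds.
#' @param seed Integer seed.
#' @param backend Backend function.
#' @return A `grid_search_result`.
#' @export
refine_grid <- function(fm, selected, grid, k = 5L, seed = 1L,
                        backend = xgb_backend()) {
  grid_search(subset_parcels(fm, selected), grid, k, seed, backend)
}
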