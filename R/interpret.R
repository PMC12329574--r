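#' Pairwise contrast specification
#'
#' One of the four design contrasts used for binary classification on
#' the selected features; the positive class is always the harder
#' condition of the pair:
#' SpH_VisE vs SpE_VisE, SpH_VisH vs SpE_VisH (speech contrasts),
#' SpE_VisH vs SpE_VisE, SpH_VisH vs SpH_VisE (visual contrasts).
#'
#' @param positive,negative Condition labels; must form one of the four
#'   contrasts above (in that orientation).
#' @return An object of class `pair_spec`.
#' @export
pair_spec <- function(positive, negative) {
  allowed <- design_pairs()
  ok <- any(vapply(allowed, function(p) {
    identical(p$positive, positive) && identical(p$negative, negative)
  }, logical(1)))
  if (!ok) {
    stop("(", positive, ", ", negative, ") is not one of the four design ",
         "contrasts (positive class must be the harder condition)")
  }
  structure(list(positive = positive, negative = negative),
            class = "pair_spec")
}

#' The four pairwise design contrasts
#'
#' @return List of four [pair_spec()] objects in the canonical order
#'   (speech contrasts first).
#' @export
design_pairs <- function() {
  raw <- list(c("SpH_VisE", "SpE_VisE"), c("SpH_VisH", "SpE_VisH"),
              c("SpE_VisH", "SpE_VisE"), c("SpH_VisH", "SpH_VisE"))
  lapply(raw, function(p) structure(list(positive = p[1], negative = p[2]),
                                    class = "pair_spec"))
}

#' Fit a pairwise binary model on the selected features
#'
#' Subsets the feature matrix to the two conditions of the pair (50 rows
#' for the default 25-subject design), restricts to the selected feature
#' columns, grid-searches the binary gradient-boosted model on
#' stratified folds, and computes per-sample Shapley attributions toward
#' the positive (harder) class from a final model trained on all pair
#' rows with the best configuration.
#'
#' @param fm The full [feature_matrix()].
#' @param pair A [pair_spec()].
#' @param selected Column indices of the selected features.
#' @param grid A [hyper_grid()].
#' @param k Folds.
#' @param seed Integer seed.
#' @param backend Backend function.
#' @return A `pair_fit`: the grid-search result, accuracy, final model,
#'   attribution matrix (rows x selected features), and the pair data.
#' @export
fit_pairwise <- function(fm, pair, selected, grid = reduced_grid(), k = 5L,
                         seed = 1L, backend = xgb_backend()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(pair, "pair_spec"))
  rows <- fm$condition %in% c(pair$positive, pair$negative)
  if (!any(fm$condition == pair$positive) ||
      !any(fm$condition == pair$negative)) {
    stop("feature matrix is missing a class of the pair")
  }
  sub <- fm$values[rows, selected, drop = FALSE]
  y <- as.integer(fm$condition[rows] == pair$positive)
  pair_fm <- structure(list(values = sub, labels = y,
                            subject = fm$subject[rows],
                            condition = fm$condition[rows],
                            parcel_ids = fm$parcel_ids[selected]),
                       class = "feature_matrix")
  gs <- grid_search(pair_fm, grid, k, seed, backend)
  model <- train_model(pair_fm, gs$best$config, seed)
  sv <- shap_values(model, pair_fm)   # n x 1 x features
  structure(list(pair = pair, search = gs, accuracy = gs$best$mean_accuracy,
                 score = round(gs$best$mean_accuracy * nrow(sub)),
                 n = nrow(sub), model = model,
                 shap = matrix(sv, nrow(sub), dim(sv)[3L],
                               dimnames = list(NULL, dimnames(sv)[[3L]])),
                 values = sub, labels = y,
                 parcel_ids = fm$parcel_ids[selected]),
            class = "pair_fit")
}

#' @export
print.pair_fit <- function(x, ...) {
  cat(sprintf("pair_fit: %s (1) vs %s (0), CV accuracy %.2f (%d/%d)\n",
              x$pair$positive, x$pair$negative, x$accuracy, x$score, x$n))
  invisible(x)
}

#' Direction-of-effect summary for a pairwise model
#'
#' For each selected feature with nonzero attribution, reports whether
#' an *elevated* or an *alleviated* response in that region predicts the
#' positive (harder) class. The direction is the sign of the Pearson
#' correlation between the feature's values and its per-sample Shapley
#' attributions toward the positive class: positive correlation means
#' larger values push predictions toward the positive class
#' ("elevated"), negative means smaller values do ("alleviated").
#' Features with all-zero attribution, or degenerate (constant)
#' features, are excluded with a notice.
#'
#' @param fit A `pair_fit` from [fit_pairwise()].
#' @return Data frame of class `direction_report` with one row per
#'   included feature: `feature`, `parcel_id`, `direction`
#'   (`"elevated"` / `"alleviated"`), and `mean_abs_shap`.
#' @export
direction_summary <- function(fit) {
  stopifnot(inherits(fit, "pair_fit"))
  feats <- colnames(fit$shap)
  rows <- lapply(seq_along(feats), function(j) {
    sv <- fit$shap[, j]
    vals <- fit$values[, j]
    mas <- mean(abs(sv))
    if (mas == 0) return(NULL)                      # no attribution
    if (stats::sd(vals) == 0 || stats::sd(sv) == 0) {
      message("feature ", feats[j], " excluded (degenerate)")
      return(NULL)
    }
    r <- stats::cor(vals, sv)
    data.frame(feature = feats[j], parcel_id = fit$parcel_ids[j],
               direction = if (r > 0) "elevated" else "alleviated",
               mean_abs_shap = mas)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(feature = character(), parcel_id = integer(),
                      direction = character(), mean_abs_shap = numeric())
  }
  out <- out[order(-out$mean_abs_shap), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("direction_report", "data.frame")
  out
}

#' Run all four pairwise contrasts and tabulate directions
#'
#' Fits the four design contrasts on the same selected feature columns
#' and stacks their direction summaries into one table (the
#' modality-general / modality-specific response structure).
#'
#' @inheritParams fit_pairwise
#' @return List with `fits` (per pair) and `table` (stacked direction
#'   report with pair, accuracy, feature, direction, mean |SHAP|).
#' @export
pairwise_directions <- function(fm, selected, grid = reduced_grid(), k = 5L,
                                seed = 1L, backend = xgb_backend()) {
  pairs <- design_pairs()
  fits <- lapply(pairs, function(p)
    fit_pairwise(fm, p, selected, grid, k, seed, backend))
  tab <- do.call(rbind, lapply(fits, function(f) {
    d <- direction_summary(f)
    if (nrow(d) == 0L) return(NULL)
    data.frame(pair = paste0(f$pair$positive, "_vs_", f$pair$negative),
               accuracy = f$accuracy, d)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
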