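#' Signal-detection sensitivity (d-prime) for old/new recognition
#'
#' `d' = z(hit rate) - z(false-alarm rate)`. Rates of exactly 0 or 1 are
#' corrected by the 1/(2N) rule (0 becomes `1/(2N)`, 1 becomes
#' `1 - 1/(2N)`) before the inverse-normal transform, so the result is
#' always finite.
#'
#' @param hits,misses Counts over the old (heard) items.
#' @param false_alarms,correct_rejections Counts over the new items.
#' @return An object of class `dprime_result` with the corrected rates,
#'   `dprime`, and the item counts.
#' @export
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  n_old <- hits + misses
  n_new <- false_alarms + correct_rejections
  if (n_old <= 0 || n_new <= 0) stop("need at least one old and one new trial")
  stopifnot(hits >= 0, misses >= 0, false_alarms >= 0,
            correct_rejections >= 0)
  correct <- function(rate, n) {
    if (rate == 0) 1 / (2 * n) else if (rate == 1) 1 - 1 / (2 * n) else rate
  }
  hr <- correct(hits / n_old, n_old)
  fr <- correct(false_alarms / n_new, n_new)
  structure(list(hit_rate = hr, fa_rate = fr,
                 dprime = stats::qnorm(hr) - stats::qnorm(fr),
                 n_old = n_old, n_new = n_new),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %.3f (hit rate %.3f over %d old, FA rate %.3f over %d new)\n",
              x$dprime, x$hit_rate, x$n_old, x$fa_rate, x$n_new))
  invisible(x)
}

#' Per-condition accuracy summaries for both tasks
#'
#' Aggregates trial-level correctness to per-subject condition means,
#' then reports the across-subject mean and SD per condition and task.
#'
#' @param trials Trial table with `subject`, `condition`,
#'   `speech_correct`, and `visual_correct` columns (as produced by
#'   [generate_behavior()]).
#' @return Data frame with `condition`, `task`, `mean`, `sd`,
#'   `n_subjects`. Conditions absent from the data trigger a notice and
#'   are omitted.
#' @export
condition_summary <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("subject", "condition", "speech_correct",
                  "visual_correct") %in% names(trials)))
  missing_cond <- setdiff(dual_task_conditions, unique(trials$condition))
  if (length(missing_cond) > 0) {
    message("no trials for condition(s): ", paste(missing_cond, collapse = ", "))
  }
  out <- list()
  for (task in c("speech", "visual")) {
    col <- paste0(task, "_correct")
    per_subj <- aggregate(trials[[col]],
                          by = list(condition = trials$condition,
                                    subject = trials$subject), FUN = mean)
    agg <- aggregate(per_subj$x, by = list(condition = per_subj$condition),
                     FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                         n = length(v)))
    out[[task]] <- data.frame(condition = agg$condition, task = task,
                              mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                              n_subjects = agg$x[, "n"])
  }
  res <- do.call(rbind, out)
  res <- res[order(res$task, match(res$condition, dual_task_conditions)), ]
  rownames(res) <- NULL
  res
}

#' Fixed-effects logistic fit of correctness on TD and difficulty
#'
#' Fits `correct ~ td * speech_hard * visual_hard` with a logit link on
#' the nontarget trials (maximum likelihood). This is a deliberately
#' simplified, fixed-effects stand-in for the crossed random-effects
#' GLMM used on real subject data: adequate for parameter-recovery
#' checks on synthetic trials, not for subject-level inference.
#'
#' Complete separation is detected (via glm's convergence diagnostics
#' and runaway coefficients) and flagged; when flagged and the glmnet
#' package is available, a lightly ridge-penalized refit is returned
#' instead of the diverged fit.
#'
#' @param trials Trial table; only rows with `is_target == 0` are used.
#' @param task `"visual"` (correct-rejection rate) or `"speech"`.
#' @return List of class `td_curve_fit`: `coefficients`, `se`, `separation`,
#'   `model` (the glm object or NULL), and `crossing_td(speech_hard,
#'   visual_hard)` giving the TD at which the fitted probability crosses
#'   0.5 for that cell.
#' @export
td_curve <- function(trials, task = c("visual", "speech")) {
  task <- match.arg(task)
  col <- paste0(task, "_correct")
  stopifnot(is.data.frame(trials), col %in% names(trials))
  d <- trials[trials$is_target == 0, , drop = FALSE]
  if (length(unique(d$td)) < 2L) stop("need at least two distinct TD values")
  df <- data.frame(correct = d[[col]], td = d$td,
                   sh = speech_hard(d$condition), vh = visual_hard(d$condition))
  fit <- suppressWarnings(stats::glm(correct ~ td * sh * vh, data = df,
                                     family = stats::binomial()))
  separation <- !fit$converged ||
    any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  coefs <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (separation && requireNamespace("glmnet", quietly = TRUE)) {
    X <- stats::model.matrix(~ td * sh * vh, df)[, -1, drop = FALSE]
    pen <- glmnet::glmnet(X, df$correct, family = "binomial", alpha = 0,
                          lambda = 1e-3)
    cf <- as.numeric(stats::coef(pen))
    coefs <- setNames(cf, c("(Intercept)", colnames(X)))
    se <- rep(NA_real_, length(coefs))
  }
  crossing_td <- function(sh = 0, vh = 0) {
    icpt <- coefs["(Intercept)"] + sh * coefs["sh"] + vh * coefs["vh"] +
      sh * vh * coefs["sh:vh"]
    slope <- coefs["td"] + sh * coefs["td:sh"] + vh * coefs["td:vh"] +
      sh * vh * coefs["td:sh:vh"]
    unname(-icpt / slope)
  }
  structure(list(coefficients = coefs, se = se, separation = separation,
                 model = if (separation) NULL else fit,
                 crossing_td = crossing_td, task = task),
            class = "td_curve_fit")
}

#' @export
print.td_curve_fit <- function(x, ...) {
  cat(sprintf("td_curve_fit (%s task)%s\n", x$task,
              if (x$separation) " [separation flagged, penalized fit]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Brain-behavior correlation
#'
#' Pearson correlation with the two-sided p-value from the t transform,
#' plus the simple regression line, for paired per-subject measures
#' (e.g., hard-easy BOLD response differences against hard-easy
#' behavioral differences).
#'
#' @param brain,behavior Paired numeric vectors, length >= 3.
#' @return List of class `correlation_result`: `r`, `r_squared`,
#'   `p_value`, `slope`, `intercept`, `n`.
#' @export
brain_behavior_corr <- function(brain, behavior) {
  stopifnot(is.numeric(brain), is.numeric(behavior),
            length(brain) == length(behavior))
  if (length(brain) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(brain) == 0 || stats::sd(behavior) == 0) {
    stop("zero variance in one of the inputs")
  }
  ct <- stats::cor.test(brain, behavior, method = "pearson")
  fit <- stats::lm(behavior ~ brain)
  structure(list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = length(brain)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (R^2 = %.3f, p = %.3g, n = %d); y = %.3g + %.3g x\n",
              x$r, x$r_squared, x$p_value, x$n, x$intercept, x$slope))
  invisible(x)
}
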