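#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run: the global seed (per-stage
#' seeds are derived from it by fixed small offsets), the design and
#' effect specifications, the hyperparameter grid, folds, patience, and
#' significance settings. Defaults mirror the study conditions: 25
#' subjects, 4 conditions, k = 5 folds, patience 5, alpha 0.05 with 4
#' Bonferroni tests. The default grid is the desk-scale [reduced_grid()];
#' pass `grid = hyper_grid()` for the full 5760-configuration search.
#'
#' @param seed Global integer seed.
#' @param design A [design_spec()].
#' @param effects An [effect_spec()].
#' @param grid A [hyper_grid()].
#' @param k Cross-validation folds.
#' @param patience Stopping patience for feature selection.
#' @param alpha Significance level.
#' @param m_tests Number of pairwise tests for Bonferroni correction.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, design = design_spec(),
                       effects = effect_spec(), grid = reduced_grid(),
                       k = 5L, patience = 5L, alpha = 0.05, m_tests = 4L) {
  stopifnot(is.numeric(seed), inherits(design, "design_spec"),
            inherits(effects, "effect_spec"), nrow(grid) >= 1L,
            k >= 2L, patience >= 1L, alpha > 0, alpha <= 1, m_tests >= 1L)
  structure(list(seed = as.integer(seed), design = design, effects = effects,
                 grid = grid, k = as.integer(k),
                 patience = as.integer(patience), alpha = alpha,
                 m_tests = as.integer(m_tests)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a flat YAML file whose keys override the [run_config()]
#' defaults; nested `design`, `effects`, and `grid` blocks are passed on
#' to [design_spec()], [effect_spec()], and [hyper_grid()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$design)) args$design <- do.call(design_spec, y$design)
  if (!is.null(y$effects)) args$effects <- do.call(effect_spec, y$effects)
  if (!is.null(y$grid)) args$grid <- do.call(hyper_grid, y$grid)
  for (f in c("k", "patience", "alpha", "m_tests")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  do.call(run_config, args)
}

stage_seed <- function(config, offset) config$seed + offset

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (trial tables and parcel
#' tables), baseline grid search, Shapley ranking, iterative feature
#' selection, hyperparameter refinement on the selected set, binomial
#' inference, pairwise contrasts with direction summaries, and
#' behavioral summaries — writing per-stage TSV/JSON outputs plus a
#' manifest recording seeds, package versions, and file hashes. A stage
#' failure halts the run with a stage-tagged error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   all file output.
#' @return A `run_report` list with every stage's result and the
#'   manifest.
#' @export
run_all <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(obj, file, writer = write_tsv) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  design <- stage("simulate_design",
                  generate_design(config$design, stage_seed(config, 1L)))
  trials <- stage("simulate_behavior",
                  generate_behavior(design, seed = stage_seed(config, 2L)))
  fm <- stage("simulate_parcels",
              generate_parcel_tables(config$effects, config$design,
                                     stage_seed(config, 3L)))
  emit(trials, "trials.tsv")
  if (!is.null(out_dir)) {
    write_feature_matrix(fm, file.path(out_dir, "features.tsv"))
  }

  baseline <- stage("baseline_grid",
                    grid_search(fm, config$grid, config$k,
                                stage_seed(config, 4L)))
  emit(baseline$results, "grid_results.tsv")

  model <- stage("train_best",
                 train_model(fm, baseline$best$config, stage_seed(config, 4L)))
  ranking <- stage("shap_rank", shap_rank(model, fm))
  sel <- stage("iterative_select",
               iterative_select(ranking$ranking, fm, baseline$best$config,
                                config$k, stage_seed(config, 5L),
                                config$patience))
  emit(sel$trace, "selection_trace.tsv")

  refined <- stage("refine_grid",
                   refine_grid(fm, sel$selected, config$grid, config$k,
                               stage_seed(config, 6L)))

  n_maps <- nrow(fm$values)
  score <- round(refined$best$mean_accuracy * n_maps)
  infer <- stage("inference",
                 inference_report(score, n_maps, 0.25,
                                  K = nrow(config$grid),
                                  alpha = config$alpha))

  pw <- stage("pairwise",
              pairwise_directions(fm, sel$selected, config$grid, config$k,
                                  stage_seed(config, 7L)))
  pair_n <- pw$fits[[1L]]$n
  pair_alpha <- bonferroni(config$alpha, config$m_tests)
  pair_threshold <- chance_threshold(pair_n, 0.5, pair_alpha)
  if (!is.null(pw$table)) emit(pw$table, "pairwise_directions.tsv")

  behav <- stage("behavior", condition_summary(trials))
  emit(behav, "behavior_summary.tsv")

  report <- list(
    config = config,
    selected_parcels = fm$parcel_ids[sel$selected],
    baseline_accuracy = baseline$best$mean_accuracy,
    selected_accuracy = sel$trace$accuracy[sel$chosen_count],
    refined_accuracy = refined$best$mean_accuracy,
    inference = infer,
    significant = score > infer$chance_threshold,
    pairwise = data.frame(
      pair = vapply(pw$fits, function(f)
        paste0(f$pair$positive, "_vs_", f$pair$negative), character(1)),
      accuracy = vapply(pw$fits, function(f) f$accuracy, numeric(1)),
      score = vapply(pw$fits, function(f) f$score, numeric(1)),
      n = pair_n,
      significant = vapply(pw$fits, function(f)
        f$score > pair_threshold, logical(1))),
    behavior = behav,
    note = paste("validation accuracies are optimistically biased: no",
                 "held-out test set is used at this sample size"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("vocattn")),
    backend = paste0("xgboost ",
                     as.character(utils::packageVersion("xgboost"))),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(design = stage_seed(config, 1L),
                       behavior = stage_seed(config, 2L),
                       parcels = stage_seed(config, 3L),
                       grid = stage_seed(config, 4L),
                       select = stage_seed(config, 5L),
                       refine = stage_seed(config, 6L),
                       pairwise = stage_seed(config, 7L)),
    grid_size = nrow(config$grid),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (!is.null(out_dir)) {
    files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(files))
    names(manifest$file_md5) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report$manifest <- manifest
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("End-to-end pipeline report\n")
  cat(sprintf("  baseline accuracy:  %.3f\n", x$baseline_accuracy))
  cat(sprintf("  selected parcels:   %s\n",
              paste(x$selected_parcels, collapse = ", ")))
  cat(sprintf("  refined accuracy:   %.3f (%s chance threshold %d/%d)\n",
              x$refined_accuracy,
              if (x$significant) "above" else "not above",
              x$inference$chance_threshold, x$inference$n))
  cat("  pairwise contrasts:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
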