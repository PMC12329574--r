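#' Condition labels of the 2x2 dual-task design
#'
#' Speech-task difficulty (8-band easy / 4-band hard vocoding) crossed
#' with visual-task difficulty (large / small target-distractor angular
#' discrepancy). The fixed numeric encoding used for classification is
#' SpE_VisE = 0, SpE_VisH = 1, SpH_VisE = 2, SpH_VisH = 3.
#'
#' @format Character vector of the four condition labels.
#' @export
dual_task_conditions <- c("SpE_VisE", "SpE_VisH", "SpH_VisE", "SpH_VisH")

condition_code <- function(condition) {
  i <- match(condition, dual_task_conditions)
  if (anyNA(i)) stop("unknown condition label")
  i - 1L
}

speech_hard <- function(condition) as.integer(condition %in% c("SpH_VisE", "SpH_VisH"))
visual_hard <- function(condition) as.integer(condition %in% c("SpE_VisH", "SpH_VisH"))

#' Dual-task design specification
#'
#' Defaults reproduce the main-run design: 25 subjects, 6 runs of 8
#' blocks with 6 trials each (288 trials per subject, 72 per condition),
#' target-distractor angular discrepancy (TD) drawn from (48, 60] degrees
#' for the easy visual task and (6, 18] for the hard one, and half of the
#' visual trials being targets.
#'
#' @param n_subjects Number of subjects.
#' @param runs Runs per subject.
#' @param blocks_per_run Blocks per run; must be divisible by 4 so each
#'   condition occupies `blocks_per_run / 4` blocks per run.
#' @param trials_per_block Trials per block.
#' @param td_easy,td_hard TD intervals `(lo, hi]` in degrees.
#' @param target_fraction Fraction of target trials per block (rounded
#'   toward targets for odd counts).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 25L, runs = 6L, blocks_per_run = 8L,
                        trials_per_block = 6L, td_easy = c(48, 60),
                        td_hard = c(6, 18), target_fraction = 0.5) {
  stopifnot(n_subjects >= 1, runs >= 1, trials_per_block >= 1,
            length(td_easy) == 2L, length(td_hard) == 2L,
            td_easy[1] < td_easy[2], td_hard[1] < td_hard[2],
            target_fraction >= 0, target_fraction <= 1)
  if (blocks_per_run %% 4L != 0L) {
    stop("`blocks_per_run` must be divisible by 4 (one 2x2 cell per quarter)")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = dual_task_conditions,
                 runs = as.integer(runs),
                 blocks_per_run = as.integer(blocks_per_run),
                 trials_per_block = as.integer(trials_per_block),
                 td_easy = td_easy, td_hard = td_hard,
                 target_fraction = target_fraction),
            class = "design_spec")
}

# block-order shuffle with no condition occupying more than two
# consecutive blocks
shuffle_blocks <- function(conditions, reps) {
  seqc <- rep(conditions, each = reps)
  repeat {
    ord <- sample(seqc)
    if (max(rle(ord)$lengths) <= 2L) return(ord)
  }
}

# uniform draw from the half-open interval (lo, hi]
runif_lh <- function(n, lo, hi) hi - stats::runif(n) * (hi - lo)

#' Generate the trial skeleton of the dual-task design
#'
#' Produces one row per trial with subject, run, block, condition, target
#' flag, and TD. Block order is pseudo-randomized per run under the
#' constraint that no condition occupies more than two consecutive
#' blocks. Within a block, `ceiling(trials_per_block * target_fraction)`
#' trials are targets (TD stored as 0 with `is_target = 1`); nontarget
#' TDs are drawn uniformly from the condition's `(lo, hi]` interval.
#'
#' @param spec A [design_spec()].
#' @param seed Integer seed; the output is reproducible given the seed.
#' @return A data frame of trial records (no responses).
#' @export
generate_design <- function(spec = design_spec(), seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(seed)
  reps <- spec$blocks_per_run %/% 4L
  n_tgt <- as.integer(ceiling(spec$trials_per_block * spec$target_fraction))
  rows <- vector("list", spec$n_subjects * spec$runs * spec$blocks_per_run)
  i <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (r in seq_len(spec$runs)) {
      order_cond <- shuffle_blocks(spec$conditions, reps)
      for (b in seq_len(spec$blocks_per_run)) {
        cond <- order_cond[b]
        is_target <- sample(rep(c(1L, 0L),
                                c(n_tgt, spec$trials_per_block - n_tgt)))
        rng <- if (visual_hard(cond) == 1L) spec$td_hard else spec$td_easy
        td <- ifelse(is_target == 1L, 0,
                     runif_lh(spec$trials_per_block, rng[1], rng[2]))
        i <- i + 1L
        rows[[i]] <- data.frame(
          subject = s, run = r, block = b,
          trial = seq_len(spec$trials_per_block),
          condition = cond, is_target = is_target, td = td)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logistic coefficients reproducing four condition means
#'
#' Returns the saturated fixed-effects coefficients (intercept, speech
#' difficulty, visual difficulty, interaction) whose logistic means equal
#' the given per-condition probabilities, with zero TD slopes.
#'
#' @param p Probabilities in condition order
#'   `SpE_VisE, SpE_VisH, SpH_VisE, SpH_VisH`.
#' @return Named numeric coefficient vector for [generate_behavior()].
#' @export
coef_from_means <- function(p) {
  stopifnot(length(p) == 4L, all(p > 0), all(p < 1))
  l <- stats::qlogis(p)  # order: EE, EH, HE, HH
  c(intercept = l[1], speech = l[3] - l[1], visual = l[2] - l[1],
    interaction = l[4] - l[3] - l[2] + l[1], td = 0, td_visual = 0)
}

#' Simulate dual-task responses on a design skeleton
#'
#' Draws `speech_correct` and `visual_correct` as Bernoulli variables
#' with logit equal to
#' `intercept + speech * speech_hard + visual * visual_hard +
#'  interaction * speech_hard * visual_hard + td * TD +
#'  td_visual * TD * visual_hard + subject_intercept`,
#' with independent Gaussian subject intercepts per task. The
#' `td_visual` term allows TD sensitivity to differ under the hard
#' visual task, where performance on small-TD nontargets approaches or
#' falls below chance while large-TD nontargets are rejected reliably.
#'
#' @param design Trial skeleton from [generate_design()].
#' @param coef_speech,coef_visual Length-6 coefficient vectors
#'   `(intercept, speech, visual, interaction, td, td_visual)`; see
#'   [coef_from_means()].
#' @param subject_sd Standard deviation of the per-subject intercepts
#'   on the logit scale (the default 0.8 yields across-subject accuracy
#'   SDs of roughly 0.1, comparable to dual-task report data).
#' @param seed Integer seed.
#' @return The design with `speech_correct` and `visual_correct` columns.
#' @export
generate_behavior <- function(design, coef_speech = coef_from_means(
                                c(0.857, 0.870, 0.533, 0.568)),
                              coef_visual = coef_from_means(
                                c(0.849, 0.655, 0.820, 0.669)),
                              subject_sd = 0.8, seed = 1L) {
  stopifnot(is.data.frame(design),
            length(coef_speech) == 6L, length(coef_visual) == 6L,
            all(is.finite(coef_speech)), all(is.finite(coef_visual)),
            subject_sd >= 0)
  set.seed(seed)
  subjects <- sort(unique(design$subject))
  int_sp <- stats::rnorm(length(subjects), 0, subject_sd)
  int_vi <- stats::rnorm(length(subjects), 0, subject_sd)
  si <- match(design$subject, subjects)
  sh <- speech_hard(design$condition)
  vh <- visual_hard(design$condition)
  lp <- function(coef, subj_int) {
    coef[1] + coef[2] * sh + coef[3] * vh + coef[4] * sh * vh +
      coef[5] * design$td + coef[6] * design$td * vh + subj_int[si]
  }
  design$speech_correct <- stats::rbinom(nrow(design), 1L,
                                         stats::plogis(lp(coef_speech, int_sp)))
  design$visual_correct <- stats::rbinom(nrow(design), 1L,
                                         stats::plogis(lp(coef_visual, int_vi)))
  design
}

#' Planted condition effects for parcel-level tables
#'
#' Describes which parcels respond to which difficulty manipulation:
#' `general_parcels` respond to both difficulties, `speech_parcels` to
#' speech difficulty and `visual_parcels` to visual difficulty. A signed
#' cross-modal suppression term (default -0.5 x `effect_size`) down-
#' modulates each modality-specific set when the *other* task is hard,
#' mirroring the resource trade-off seen in modality-specific regions.
#'
#' @param n_parcels Number of parcels (columns of the feature matrix).
#' @param general_parcels,speech_parcels,visual_parcels Disjoint integer
#'   index sets within `1:n_parcels`.
#' @param effect_size Standardized mean shift per difficulty step.
#' @param subject_sd SD of stable per-subject, per-parcel offsets.
#' @param noise_sd Residual SD.
#' @param suppression Cross-modal modulation as a multiple of
#'   `effect_size` (0 disables it).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(n_parcels = 100L, general_parcels = 1:4,
                        speech_parcels = 5:8, visual_parcels = 9:12,
                        effect_size = 2.0, subject_sd = 0.5, noise_sd = 1.0,
                        suppression = -0.5) {
  sets <- list(general_parcels, speech_parcels, visual_parcels)
  idx <- unlist(sets)
  stopifnot(n_parcels >= 1, effect_size >= 0, subject_sd >= 0, noise_sd >= 0)
  if (length(idx) > 0) {
    if (any(idx < 1) || any(idx > n_parcels)) {
      stop("parcel index sets must lie within 1:n_parcels")
    }
    if (anyDuplicated(idx)) stop("parcel index sets must be disjoint")
  }
  structure(list(n_parcels = as.integer(n_parcels),
                 general_parcels = as.integer(general_parcels),
                 speech_parcels = as.integer(speech_parcels),
                 visual_parcels = as.integer(visual_parcels),
                 effect_size = effect_size, subject_sd = subject_sd,
                 noise_sd = noise_sd, suppression = suppression),
            class = "effect_spec")
}

#' Per-parcel condition effect profile implied by an effect_spec
#'
#' @param effects An [effect_spec()].
#' @return A 4 x n_parcels matrix of planted condition means (rows in
#'   condition order).
#' @export
planted_means <- function(effects) {
  stopifnot(inherits(effects, "effect_spec"))
  m <- matrix(0, 4L, effects$n_parcels,
              dimnames = list(dual_task_conditions, NULL))
  es <- effects$effect_size
  sup <- effects$suppression * es
  for (cond in dual_task_conditions) {
    sh <- speech_hard(cond); vh <- visual_hard(cond)
    m[cond, effects$general_parcels] <- es * (sh + vh)
    m[cond, effects$speech_parcels] <- es * sh + sup * vh
    m[cond, effects$visual_parcels] <- es * vh + sup * sh
  }
  m
}

#' Generate a parcel-level feature matrix with planted effects
#'
#' Emulates, at parcel resolution, the per-subject per-condition t-value
#' maps that feed the classification pipeline: one row per subject x
#' condition (100 rows for the default 25-subject design), one column
#' per parcel. Each value is
#' `subject offset + planted condition mean + Gaussian noise`, where the
#' subject offset is a stable per-subject, per-parcel deviation.
#'
#' @param effects An [effect_spec()].
#' @param spec A [design_spec()] (only `n_subjects` is used).
#' @param seed Integer seed.
#' @return A [feature_matrix()].
#' @export
generate_parcel_tables <- function(effects = effect_spec(),
                                   spec = design_spec(), seed = 1L) {
  stopifnot(inherits(effects, "effect_spec"), inherits(spec, "design_spec"))
  set.seed(seed)
  ns <- spec$n_subjects
  np <- effects$n_parcels
  cond_mean <- planted_means(effects)
  subj_offset <- matrix(stats::rnorm(ns * np, 0, effects$subject_sd), ns, np)
  subject <- rep(seq_len(ns), each = 4L)
  condition <- rep(dual_task_conditions, ns)
  values <- subj_offset[subject, , drop = FALSE] +
    cond_mean[condition, , drop = FALSE] +
    matrix(stats::rnorm(ns * 4L * np, 0, effects$noise_sd), ns * 4L, np)
  feature_matrix(values, subject = subject, condition = condition,
                 parcel_ids = seq_len(np))
}

# --- sentence pool ------------------------------------------------------

#' Generate the pseudo-sentence pool
#'
#' Emits 606 uniquely keyed sentence records: 336 tagged `BKB` and 270
#' tagged `ASL`, mirroring the two short-sentence corpora the speech task
#' draws from. Supports sampling without replacement via
#' [draw_sentences()] and the post-scan old/new split via
#' [postscan_split()].
#'
#' @return Data frame with `sentence_id` and `corpus` columns.
#' @export
generate_sentence_pool <- function() {
  data.frame(
    sentence_id = c(sprintf("BKB_%03d", 1:336), sprintf("ASL_%03d", 1:270)),
    corpus = rep(c("BKB", "ASL"), c(336L, 270L)))
}

#' Draw unique sentences from the pool
#'
#' @param pool Sentence pool from [generate_sentence_pool()].
#' @param n Number of sentences to draw.
#' @param seed Integer seed.
#' @param exclude Sentence ids already used (sampling is without
#'   replacement across calls when previous draws are passed here).
#' @return A subset of `pool` with `n` rows.
#' @export
draw_sentences <- function(pool, n, seed = 1L, exclude = character()) {
  stopifnot(is.data.frame(pool), n >= 1)
  avail <- pool[!pool$sentence_id %in% exclude, , drop = FALSE]
  if (n > nrow(avail)) {
    stop(sprintf("sentence pool exhausted: %d requested, %d available",
                 n, nrow(avail)))
  }
  set.seed(seed)
  out <- avail[sample.int(nrow(avail), n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the post-scan old/new recognition fixture
#'
#' From one subject's main-run sentence assignment, samples 24 heard
#' ("old") sentences per condition (96 total) and 32 unheard ("new")
#' sentences from the remainder of the pool, in randomized order.
#'
#' @param main_draw Data frame with `sentence_id` and `condition` for the
#'   sentences presented in the main runs.
#' @param pool Sentence pool from [generate_sentence_pool()].
#' @param seed Integer seed.
#' @param n_old_per_condition,n_new Fixture sizes.
#' @return Data frame with `sentence_id`, `condition` (`NA` for new
#'   items), and `is_old`.
#' @export
postscan_split <- function(main_draw, pool, seed = 1L,
                           n_old_per_condition = 24L, n_new = 32L) {
  stopifnot(is.data.frame(main_draw),
            all(c("sentence_id", "condition") %in% names(main_draw)))
  set.seed(seed)
  old <- do.call(rbind, lapply(dual_task_conditions, function(cond) {
    cand <- main_draw[main_draw$condition == cond, , drop = FALSE]
    if (nrow(cand) < n_old_per_condition) {
      stop("not enough main-run sentences in condition ", cond)
    }
    cand[sample.int(nrow(cand), n_old_per_condition), c("sentence_id", "condition")]
  }))
  old$is_old <- 1L
  unused <- pool[!pool$sentence_id %in% main_draw$sentence_id, , drop = FALSE]
  if (nrow(unused) < n_new) stop("sentence pool exhausted for new items")
  new <- data.frame(
    sentence_id = unused$sentence_id[sample.int(nrow(unused), n_new)],
    condition = NA_character_, is_old = 0L)
  out <- rbind(old, new)
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a data frame as a TSV file
#'
#' Plain-text serialization used throughout the pipeline; byte-for-byte
#' reproducible for identical inputs.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
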