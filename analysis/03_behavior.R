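#!/usr/bin/env Rscript
# Behavioral analytics on the simulated trials: condition accuracy
# summaries, old/new recognition d-prime, TD response curves, and a
# brain-behavior correlation.

suppressPackageStartupMessages(library(vocattn))
trials <- utils::read.delim("results/trials.tsv")
fm <- read_feature_matrix("results/features.tsv")
dir.create("results", showWarnings = FALSE)

cs <- condition_summary(trials)
write_tsv(cs, "results/behavior_summary.tsv")
cat("Condition accuracies (mean [SD] across subjects):\n")
for (i in seq_len(nrow(cs))) {
  cat(sprintf("  %-9s %-7s %.3f [%.2f]\n", cs$condition[i], cs$task[i],
              cs$mean[i], cs$sd[i]))
}

# old/new recognition: per-subject, per-condition sensitivity drawn
# around speech-difficulty-dependent targets, neutral criterion
dp_target <- c(SpE_VisE = 0.40, SpE_VisH = 0.40, SpH_VisE = 0.20,
               SpH_VisH = 0.28)
set.seed(104)
dp_rows <- list()
for (s in unique(trials$subject)) {
  for (cond in dual_task_conditions) {
    d_true <- rnorm(1, dp_target[[cond]], 0.15)
    hits <- rbinom(1, 24, pnorm(d_true / 2))
    fas <- rbinom(1, 8, pnorm(-d_true / 2))
    r <- dprime(hits, 24 - hits, fas, 8 - fas)
    dp_rows[[length(dp_rows) + 1]] <-
      data.frame(subject = s, condition = cond, dprime = r$dprime)
  }
}
dp <- do.call(rbind, dp_rows)
write_tsv(dp, "results/dprime.tsv")
dp_mean <- aggregate(dprime ~ condition, dp, mean)
cat("Mean recognition d' by condition:\n")
print(dp_mean, row.names = FALSE)

fit <- td_curve(trials, "visual")
cat("TD curve (visual correct rejection), fixed-effects logistic:\n")
print(round(fit$coefficients, 4))

# per-subject speech-hard minus speech-easy contrasts, brain vs behavior
subj <- sort(unique(fm$subject))
sp_cols <- 5:8  # speech-responsive parcels in the default effect spec
brain_diff <- vapply(subj, function(s) {
  hard <- fm$values[fm$subject == s & fm$condition %in%
                      c("SpH_VisE", "SpH_VisH"), sp_cols]
  easy <- fm$values[fm$subject == s & fm$condition %in%
                      c("SpE_VisE", "SpE_VisH"), sp_cols]
  mean(hard) - mean(easy)
}, numeric(1))
acc <- aggregate(speech_correct ~ subject + condition, trials, mean)
behav_diff <- vapply(subj, function(s) {
  a <- acc[acc$subject == s, ]
  mean(a$speech_correct[a$condition %in% c("SpH_VisE", "SpH_VisH")]) -
    mean(a$speech_correct[a$condition %in% c("SpE_VisE", "SpE_VisH")])
}, numeric(1))
corr <- brain_behavior_corr(brain_diff, behav_diff)
jsonlite::write_json(unclass(corr), "results/brain_behavior_corr.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("Brain-behavior correlation (speech hard-easy): r = %.3f, p = %.3g\n",
            corr$r, corr$p_value))
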