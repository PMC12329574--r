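#!/usr/bin/env Rscript
# Pairwise binary models on the selected features: accuracy against the
# Bonferroni-corrected binomial chance level, and direction-of-effect
# summaries (elevated vs alleviated response predicting the harder
# condition).

suppressPackageStartupMessages(library(vocattn))
fm <- read_feature_matrix("results/features.tsv")
selinfo <- jsonlite::read_json("results/selected_features.json")
selected <- match(unlist(selinfo$selected_parcels), fm$parcel_ids)

pw <- pairwise_directions(fm, selected, reduced_grid(), k = 5, seed = 108)
write_tsv(pw$table, "results/pairwise_directions.tsv")

alpha_corr <- bonferroni(0.05, 4)
n_pair <- pw$fits[[1]]$n
thr <- chance_threshold(n_pair, 0.5, 0.05)
thr_corr <- chance_threshold(n_pair, 0.5, alpha_corr)
cat(sprintf("Binary chance thresholds over %d maps: %d (alpha 0.05), %d (alpha %.4f)\n",
            n_pair, thr, thr_corr, alpha_corr))
for (f in pw$fits) {
  cat(sprintf("  %s (1) vs %s (0): accuracy %.2f (%d/%d), tail p = %.3g\n",
              f$pair$positive, f$pair$negative, f$accuracy, f$score, f$n,
              tail_p(f$score, f$n, 0.5)))
}
cat("Direction table written to results/pairwise_directions.tsv\n")
cat("  (direction = response level in the region predicting the harder condition)\n")
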