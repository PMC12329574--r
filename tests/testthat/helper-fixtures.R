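# Shared fixtures, built in code at test time.

# A small planted-signal feature matrix: `n_subjects` subjects, the
# default 12 informative parcels among `n_parcels`.
small_fm <- function(seed = 1L, n_subjects = 10L, n_parcels = 20L,
                     effect_size = 2, noise_sd = 1) {
  es <- if (n_parcels >= 12L) {
    effect_spec(n_parcels = n_parcels, effect_size = effect_size,
                noise_sd = noise_sd)
  } else {
    effect_spec(n_parcels = n_parcels, general_parcels = 1:2,
                speech_parcels = 3:4, visual_parcels = 5:6,
                effect_size = effect_size, noise_sd = noise_sd)
  }
  generate_parcel_tables(es, design_spec(n_subjects = n_subjects),
                         seed = seed)
}

# Pure-noise feature matrix (no planted effects).
noise_fm <- function(seed = 1L, n_subjects = 10L, n_parcels = 20L) {
  generate_parcel_tables(
    effect_spec(n_parcels = n_parcels, general_parcels = integer(),
                speech_parcels = integer(), visual_parcels = integer(),
                effect_size = 0),
    design_spec(n_subjects = n_subjects), seed = seed)
}

# A single fast boosting configuration from the tested value lists.
fast_config <- function() {
  hyper_grid(colsample_bytree = 0.7, gamma = 0, learning_rate = 0.13,
             max_depth = 2, n_estimators = 50)
}

informative_parcels <- function(effects) {
  sort(c(effects$general_parcels, effects$speech_parcels,
         effects$visual_parcels))
}
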