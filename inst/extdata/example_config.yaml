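# Example end-to-end pipeline configuration for read_run_config().
# Numeric defaults elsewhere mirror the study design (25 subjects, 4
# conditions, k = 5, patience = 5, alpha = 0.05, 4 Bonferroni tests);
# this desk-scale example runs in seconds.
seed: 7
design:
  n_subjects: 10
effects:
  n_parcels: 20
  effect_size: 2.5
grid:
  colsample_bytree: [0.3, 0.7]
  gamma: 0
  learning_rate: [0.07, 0.13]
  max_depth: [2, 4]
  n_estimators: 50
k: 5
patience: 5
alpha: 0.05
m_tests: 4
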