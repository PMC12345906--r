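# Example grid manifest: a reduced search space for quick runs.
# Omitted keys fall back to the shipped defaults (the full 4704-config grid).
scalers: [standard, none]
selectors:
  - [{kind: correlation, threshold: 0.9}]
  - [{kind: mrmr, k: 10}]
  - [{kind: lasso, penalty: 1.0}]
  - [{kind: correlation}, {kind: mrmr, k: 10}, {kind: lasso}]
resampling:
  methods: [random, smote]
  levels: [0, 0.5, 1.0]
  k_neighbors: 5
classifiers: [logistic_regression, random_forest, naive_bayes]
protocol:
  n_splits: 10
  test_fraction: 0.1
  fold_cutoff: 100
  wp_threshold: 0.7
  seed: 42
  aggregation_mode: pooled
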