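# Example pipeline configuration for pipeline_config_from_yaml().
seed: 1
climate_years: [1985, 2016]
evi_years: [2000, 2016]
trend_alpha: 0.05
n_runs: 20
sample_size: 10000
landscape:
  n_rows: 100
  n_cols: 100
  smoothing_length: 3
  subgrid_size: 33
spei:
  timescales: [3, 6, 12]
  end_month: 8
  method: log-logistic
sensitivity:
  min_baseline_years: 3
  min_drought_years: 1
brt:
  tree_complexity: 5
  bag_fraction: 0.5
  learning_rate: 0.005
  step_size: 50
  max_trees: 10000
  cv_folds: 10
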