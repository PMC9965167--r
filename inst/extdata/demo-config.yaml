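# Demonstration pipeline configuration for `maizefuse run --config ...`.
# Stage defaults mirror the reference survey conditions (3 cm GSD,
# 176 x 25 crop window, 60/20/20 split, Adam lr 0.001 decayed every 5
# epochs); the sizes here are reduced for a quick desk run.
seed: 1
out_dir: maizefuse_demo
simulate:
  n_plots: 60
  plots_per_block: 6
  n_bands: 60
  n_block_cols: 1
  effect_scale: 1
prep:
  margin: 5
  use_truth_mask: false
ndsi:
  enabled: true
  traits: [dry_grain_yield, total_plant_n]
features:
  enabled: true
train_ml:
  enabled: true
  regressor: rfr
  traits: [dry_grain_yield, total_plant_n]
  feature_set: hyper_dsm
train_dl:
  enabled: true
  tasks: [dry_grain_yield, total_plant_n]
  modalities: [hyperspectral, lidar_height, lidar_intensity]
  n_crops: 5
  max_epochs: 8
  bins: 6
evaluate:
  enabled: true
  moran_k: 8
  n_permutations: 999
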