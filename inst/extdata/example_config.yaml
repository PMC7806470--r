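# Example strokeseg pipeline configuration.
# Top-level keys map to pipeline_config(); the phantom map to phantom_config().
phantom:
  grid: [64, 64, 24]
  voxel_dims: [0.25, 0.25, 1.0]
  n_train: 12
  n_test: 20
  include_edema: true
  include_artifact: true
  t2w_scale_shift: [2.0, 10.0]
K_range: [2, 8]
eps: 0.01
n_trees: 100
min_leaf: 1
adc_cutoff: 680
t2w_factor: 1.25
binarize_threshold: 0.5
median_filter: false
transfer: true
seed: 20240101
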