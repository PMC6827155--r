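# Default run configuration.
# The training block carries the detector hyperparameters used at full
# scale; the proposal-box counts belong to the proposal stage of such a
# detector and are shipped for completeness only.
seed: 1
log_level: info

training:
  learning_rate: 0.001
  momentum: 0.9
  gamma: 0.1
  weight_decay: 0.0001
  batch_size: 64
  num_seed_boxes: 10000
  num_output_boxes: 2000

synth:
  width: 256
  height: 256
  fov_radius_frac: 0.47
  n_mas: 8
  illumination: normal
  vessel_density: 6
  min_distance: 1

equalization:
  clahe_clip_limit: 2.0
  clahe_tiles: [8, 8]
  brightness_low: 40
  brightness_high: 180
  reject_on_quality: true

voc:
  window: 128
  stride: 128
  min_diameter: 5
  roi_fraction_min: 0.1
  test_fraction: 0.25

fusion:
  fused_channels: 256
  upsample_mode: bilinear
  backbone_name: demo

loss:
  lambda: 1.0
  attention_reduction: sum
  score_map_stride: 4

detector:
  p_class_tp: 0.9
  n_fp_on_vessel: 5
  p_class_fp: 0.4
  fp_size: 12

screening:
  c_p: 100
  alpha: 0.9
  beta: 0.1
  step: 5
  vote_threshold: 0.8
  on_vessel_zero: true

eval:
  iou_threshold: 0.5
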