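iso_spacing: 1.0
projection:
  mode: mip
  slab_frac: 0.5
sigma: 15.0
loc_windows:
- - 1000.0
  - 2000.0
- - 400.0
  - 500.0
- - 800.0
  - 1900.0
loc_grid:
- 128
- 256
l1_window:
- -1024.0
- 500.0
l3_windows:
- - -1024.0
  - 2048.0
- - -190.0
  - -30.0
- - 40.0
  - 100.0
seg_grid: 512
postprocess:
  modal_iterations: 0
k: 5
model:
  loc_base: 6
  seg_base: 8
training:
  lr_loc: 1.0e-03
  lr_seg: 3.0e-04
  batch: 8
  epochs_loc: 60
  epochs_seg: 40
  patience: 10
  validation_frac: 0.1
  dice_weight: 1.0
  seed: 42
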