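{
  "seed": 1,
  "render": true,
  "cohort": {
    "n_per_group": 3,
    "field_um": 300,
    "pixel_size_um": 3,
    "particle_contrast": 2,
    "n_slices": 1,
    "subject_sd": 0.15
  },
  "segmentation": {
    "kernel_um": 50,
    "lower_bound": 1.15
  },
  "window": {
    "window_um": 100,
    "overlap_frac": 0.5
  }
}
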