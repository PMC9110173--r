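# Demo configuration: two synthetic phantom subjects measured end-to-end,
# plus a default synthetic cohort comparison.
seed: 1
output_dir: airwayct-demo-out
alpha: 0.05
area_summary: min
segmentation:
  gray_levels: 256
  window_low: 0
  window_high: 255
  polarity: dark
  erosion_element: cross
  erosion_iterations: 1
  connectivity: 26
phantom:
  n_subjects: 2
  shape: [48, 48, 44]
  noise_sd: 8
  collapse_targets:
    nasopharyngeal: 0.0
    posterior_palatal: 0.2
    retrolingual: 0.4
    laryngopharyngeal: 0.6
cohort:
  n_per_group: 30
  null_effects: false
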