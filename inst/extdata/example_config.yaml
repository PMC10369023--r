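# End-to-end pipeline configuration (all keys optional; package defaults
# apply to anything omitted).
seed: 1
observer:
  weber_fractions: [0.05, 0.05, 0.05]
  luminance_weber: 0.05
  acuity_cpd: 3
acuity:
  k_cycle_to_sigma: 2
ranked_filter:
  radius_px: 2
  n_iter: 5
  keep_fraction: 0.5
leia:
  block_px: 2
pipeline:
  distances_cm: [2, 5, 10, 30]
cohort:
  n_species: 13
  individuals_per_species: 4   # omit to use the full 226-individual design
  image_size_px: 64
stats:
  enabled: true
  df_method: satterthwaite
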