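# Example qIT screen configuration.
# Omit `input` to run on a simulated screen; point it at a long-format
# time-course CSV (plate, well, fragment_id, target_id, role, replicate,
# time_h, fluorescence_au) to analyse real plate-reader data.
seed: 7
output_dir: qit_results
background_au: 50
thresholds:
  mode: fixed       # or "derived" for data-driven FDR-bounded cutoffs
  upper: 3
  lower: 0.3
  target_fdr: 0.025
fit:
  k_lower: 1.0e-5   # 1/h
  k_upper: 100      # 1/h
simulator:
  n_fragments: 138
  n_protein_targets: 7
  n_replicates: 2
  noise_cv: 0.05
  hit_fraction: 0.05
  retarded_fraction: 0.05
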