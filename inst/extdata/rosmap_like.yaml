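# Cohort-scale preset mirroring the emulated study's dimensions
# (589 samples, 23,056 genes). Cluster-scale: expect hours, not minutes.
n_genes: 23056
n_case: 354
n_control: 235
baseline_logmean: {mean: 4.0, sd: 2.0}
dispersion_gamma: {shape: 2.0, scale: 0.05}
de_fraction: 0.17
de_log2fc: {mean: 0.0, sd: 0.4}
n_batches: 2
batch_log2fc_sd: 0.15
depth_log_sd: 0.2
sentinel:
  case_log2fc: 0.5338
  n_outlier_controls: 4
  share: 0.55
  base_mean: 2.0
  control_dispersion: 3.5
  case_dispersion: 0.5
seed: 1
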