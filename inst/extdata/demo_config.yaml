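# Reduced demonstration configuration for the file-based pipeline:
# 6 simulated subjects, 2 runs of 5 twelve-second trials, two 8-voxel ROIs.
seed: 42
ps_method: pairwise_mean
fit_threshold: 0.7
simulate:
  n_subjects: 6
  link_strength: 0.6
  rho_range: [0.05, 0.65]
  design:
    n_runs: 2
    n_items: 5
    n_voxels_roi: 8
    n_sessions: 9
glm:
  tr_s: 2
  highpass_s: 100
  hrf_dt_s: 0.1
  add_derivatives: true
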