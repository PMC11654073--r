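# Shared configuration for the numbered analysis scripts: a 12-subject
# synthetic cohort at reduced imaging scale (4 runs of 8 twelve-second
# trials, two 60-voxel ROIs), with the pattern-similarity/learning-rate
# link set to 0.6.
seed: 20240901
out_dir: results/cohort
ps_method: pairwise_mean
fit_threshold: 0.7
simulate:
  n_subjects: 12
  link_strength: 0.6
  rho_range: [0.05, 0.65]
  design:
    n_runs: 4
    n_items: 8
    n_voxels_roi: 60
    n_sessions: 9
glm:
  tr_s: 2
  highpass_s: 100
  hrf_dt_s: 0.1
  add_derivatives: true
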