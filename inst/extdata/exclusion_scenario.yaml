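# Synthetic behavioral scenario for the goodness-of-fit inclusion rule:
# a 26-participant, 9-session cohort whose RT noise (148 ms) is tuned so
# that, on average, four power-law fits fall below the R^2 = 0.7 inclusion
# threshold, i.e. an expected survivor count of 22.
n_subjects: 26
n_sessions: 9
mu_a: 2000
sd_a: 150
mu_b: 0.3
sd_b: 0.08
rt_noise_sd_ms: 148
rt_floor_ms: 200
threshold: 0.7
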