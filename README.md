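# pslearn

Does reading a brand-new script with your native-language brain circuits
help you learn it? `pslearn` is an R implementation of the analysis chain
behind that question for cognitive-neuroimaging researchers: it measures,
per participant and region of interest (ROI), the **cross-language neural
pattern similarity** (PS) between multivoxel activation patterns evoked by
native-language words and by novel artificial-language words before
training, estimates each participant's **rate of learning** from behavioral
training sessions, and correlates the two across participants. Because
participant-level fMRI data are rarely redistributable, the package includes
a first-class synthetic-data generator with known ground truth, and every
estimator is validated by parameter recovery.

## The model

For items i of the native language (CW) and j of the novel language (ALW),
with per-item multivoxel activation patterns estimated in an ROI:

- **Single-item GLM** — each item is one regressor (stimulus boxcar ⊗
  double-gamma HRF, sampled at TR = 2 s); data and design are high-pass
  filtered (100-s discrete-cosine drift basis), fit by OLS per voxel, and
  item betas are averaged across repeated runs of each condition.
- **Pattern similarity** — pairwise variant:
  `PS = mean over (i, j) of arctanh( cor(beta_i, beta_j) )`
  across voxels; averaged variant: one `arctanh(cor(mean CW pattern, mean
  ALW pattern))`.
- **Learning curve** — per-session mean RTs follow the power law
  `y = a · x^(−b)`; `a` is initial performance (ms), `b` the learning
  rate, fit by nonlinear least squares with a log-log initialization.
  Participants with `R² < 0.7` (strict) are excluded.
- **Brain-behavior link** — per ROI, Pearson `r` between PS and `b` over
  included participants, two-tailed `p` on `n − 2` df; plus a one-way
  repeated-measures ANOVA (`F(T−1, (T−1)(N−1))`, partial η²) for the
  training effect.

The simulator controls the expected cross-language correlation exactly
(each pattern is `√ρ·c + √(1−ρ)·e` with a per-subject common vector `c`)
and couples the learning rate to `ρ` with a preset cohort-level link, so
the whole chain can be checked end to end against ground truth. See
`vignettes/pattern-similarity-learning.Rmd` for the full methods account.

## Worked example

The numbered scripts under `analysis/` run a 12-subject synthetic study end
to end (simulate → GLM → similarity → learning curves → correlation),
writing their tables under `results/cohort/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_first_level_glm.R
Rscript analysis/03_pattern_similarity.R
Rscript analysis/04_learning_curves.R
Rscript analysis/05_brain_behavior.R
```

Output of the last three steps on the committed configuration
(`analysis/config.yaml`, seed 20240901):

```
Computed pairwise_mean similarity for 24 subject x ROI cells
  left_fusiform    mean ps_z = 0.373 (range 0.061 to 0.600)
  right_fusiform   mean ps_z = 0.096 (range 0.047 to 0.149)
  correlation of left-fusiform ps_z with true rho: 0.960

Training effect on reaction times:
  F(8, 88) = 191.890, p = 2.76e-52, partial eta^2 = 0.946
Fitted 12 learning curves: a in [1772, 2064] ms, b in [0.19, 0.42]
  inclusion rule R^2 >= 0.7: 12 kept, 0 excluded (mean R^2 of kept = 0.98)

ROI-wise correlation of cross-language pattern similarity with learning rate:
  left_fusiform    r = +0.587, p = 0.045, n = 12
  right_fusiform   r = -0.406, p = 0.191, n = 12
Preset link between shared fraction and learning rate: 0.60
```

Reading the output: the target (left fusiform) ROI was simulated so each
subject's patterns share a subject-specific signal fraction between
languages; its estimated similarity tracks that truth (r = 0.96), and the
brain-behavior correlation recovers the preset 0.6 link as a positive,
significant `r` in the target ROI while the control ROI — whose similarity
is the same low value for everyone — shows no systematic association. The
ANOVA confirms RTs drop across the nine training sessions.

The same chain is available programmatically: `simulate_cohort()` →
`analyze_cohort()`, or the file-based `run_pipeline()` which reads a YAML
configuration, runs every stage, and writes a manifest of content digests
for reproducibility.

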