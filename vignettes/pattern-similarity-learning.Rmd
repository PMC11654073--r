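---
title: "Cross-language pattern similarity and novel word learning: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-language pattern similarity and novel word learning: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the estimand

When literate adults learn to read words in a new script, do they do better
if their brain treats the new words the way it treats their native
language? `pslearn` implements the analysis chain that operationalizes this
question: it quantifies, per participant and region of interest (ROI), the
*cross-language pattern similarity* (PS) between multivoxel activation
patterns evoked by native-language words (CW) and by novel artificial-language
words (ALW) measured *before* training, and relates that similarity to the
participant's *rate of learning* estimated from behavioral training sessions.
The estimand is the across-participant Pearson correlation between PS and
learning rate, per ROI.

Because individual-participant fMRI data are not redistributable, the package
pairs the estimation chain with a synthetic-data generator in which the true
cross-language similarity, the true learning parameters, and the true
PS-to-learning link are all known. Every estimator is validated by parameter
recovery against that ground truth.

## The estimation chain

**Single-item GLM.** Each item in each run is modeled as a single regressor:
the item's stimulus boxcar on a 0.1-s grid, convolved with a double-gamma
hemodynamic response function (peak gamma at 6 s minus a 16-s undershoot
scaled by 1/6, peak-normalized), sampled at the TR (2 s). Temporal
derivatives of the task regressors and any supplied motion columns are
covariates of no interest; filler events share one nuisance regressor. Data
and design are high-pass filtered at a 100-s cutoff, then each voxel is fit
by ordinary least squares. For an item-versus-baseline contrast the contrast
estimate is the item's beta, so the of-interest betas are the single-item
activation patterns. Betas are averaged across the repeated runs of each
condition to raise the single-trial signal-to-noise ratio.

**Pattern similarity.** Within an ROI (a voxel set, canonicalized to
lexicographic (x, y, z) order so file orderings cannot change results), two
variants are provided:

* *pairwise mean* — Pearson-correlate every CW x ALW item pair across
  voxels, Fisher-z transform each correlation (z = arctanh r), and average
  the n1 x n2 z values into one scalar;
* *averaged pattern* — average each language's item patterns into one mean
  pattern and take a single Fisher-z-transformed correlation.

The pairwise variant suits a slow event-related session with one condition
per run; the averaged variant suits a rapid jittered session where item-level
estimates are noisier.

**Learning curve.** Per-session mean reaction times are fit with the power
law y = a·x^(-b), a the initial performance (ms) and b the dimensionless
learning rate, by nonlinear least squares on the raw-RT scale, initialized
from the log-log regression closed form. Goodness of fit is
R² = 1 − SS_res/SS_tot on the raw scale, and participants with R² strictly
below 0.7 are excluded from the brain-behavior analysis ("lower than"
implies strict inequality; a fit of exactly 0.7 is kept).

**Group statistics.** The training effect is checked with a one-way
repeated-measures ANOVA (session effect tested against the
subject-by-session interaction, F with (T−1, (T−1)(N−1)) df, partial eta
squared as SS_session/(SS_session+SS_error), no sphericity correction). The
headline analysis is the per-ROI Pearson correlation between PS and b over
included participants, with a two-tailed p from the t transform on n−2 df,
reported for every requested ROI with no multiple-comparison correction
across ROIs — both choices mirror how such analyses are conventionally
reported for a small set of a-priori ROIs.

## The synthetic cohort

The generator emulates two session designs. The slow event-related design
presents 20 items of one condition per run across 6 runs (3 per language),
each trial a fixed 12-s budget: 1 s fixation, 3 s stimulus, 8 s unmodeled
orientation-judgment window; the session totals 24 minutes. The jittered
design presents 30 items in each of 3 conditions twice, plus 9 fillers
(189 presentations of 600 ms), with inter-stimulus intervals drawn from a
truncated geometric-like distribution on {1, …, 5} s tuned to a 2-s mean —
the minimal discrete family consistent with a stated range and mean. The
self-paced orientation window is simulated as a fixed 8-s interval because
the per-trial budget and session total pin it down; fixation and
orientation intervals are implicit baseline rather than regressors, the
conventional treatment when a publication does not state otherwise.

Cross-language similarity is controlled by a shared-signal construction:
one common voxel vector c is drawn per subject, and every item pattern in
both languages is √ρ·c + √(1−ρ)·e with independent unit-variance item noise
e, so the expected Pearson correlation of any cross-language pair is exactly
ρ. BOLD runs follow the same forward model the GLM assumes — amplitude
times HRF-convolved boxcar — plus a linear drift and stationary AR(1)
Gaussian noise (marginal sd 0.6 signal units, lag-1 coefficient 0.3, drift
0.05 per volume by default; single-trial response amplitudes have unit
variance, so this is a moderately noisy single-trial regime). Learning
series follow y = a·x^(-b) plus Gaussian noise (a ~ N(2000, 150²) ms,
b ~ N(0.3, 0.08²), session noise 50 ms, floored at 200 ms), with an
accuracy column generated as a saturating series reaching ≈0.95 by session
nine; the accuracy column mirrors real behavioral tables but is never fit.
At the cohort level, b is coupled to ρ as
b = μ_b + σ_b·(λ·z(ρ) + √(1−λ²)·ε), which makes the expected correlation
between ρ and b equal the preset link λ.

Two ROIs are simulated: the target region carries the subject-specific ρ,
and a control region carries a fixed low ρ of 0.1 for every subject, so the
brain-behavior correlation should appear in the target ROI only.

What the generator does *not* emulate: spatial autocorrelation and
smoothing, head motion, physiological noise, non-Gaussian or non-stationary
noise, BOLD nonlinearity at short SOAs, and item-level semantic structure
(all cross-language pairs share one common component rather than a
word-specific geometry). Passing recovery tests therefore demonstrates that
the estimators are correct and calibrated under the stated model, not that
the pipeline is robust to every artifact of real fMRI data.

## Numerical choices

* **High-pass filter.** FSL-style nonlinear (Gaussian-weighted running
  line) filtering is replaced by projection onto a drift basis — constant,
  linear trend, and discrete-cosine components with period above the 100-s
  cutoff. This is deterministic, spectrally equivalent at these run
  lengths, and makes "filter both sides then OLS" exactly equal to OLS with
  the basis appended (a tested identity). The linear term is included so a
  pure linear drift is removed exactly.
* **No prewhitening.** Only the point estimates feed the similarity
  analysis, and OLS betas are unbiased under AR(1) noise; standard errors
  of single-run betas are never used.
* **Convolution grid.** Regressors are built on a 0.1-s grid and sampled at
  the TR, since 600-ms stimuli and jittered onsets are not TR-aligned. The
  grid step must divide the TR.
* **Degenerate correlations.** Fisher z is undefined at |r| = 1, so the
  similarity functions raise an error there by default; an explicit
  `clip` argument clamps to 1 − 1e-12 for deliberately degenerate synthetic
  inputs. Zero-variance patterns are reported with the offending item index.
* **Aggregation of pair z values** to the participant scalar is the
  unweighted mean over all n1 x n2 pairs, the field convention; all pairs
  are included (no exclusion of translation-equivalent pairs).
* **Raw betas** enter the correlations without prior z-scoring of patterns;
  Pearson correlation standardizes internally.
* **Constant RT series** have SS_tot = 0; the fit is defined as the exact
  degenerate solution b = 0, R² = 1.
* **Optimizer failures** after the log-linear start and four perturbed
  restarts yield a flagged fit with R² = −∞, which the inclusion rule then
  excludes; the optimizer's residual sum of squares is tested never to
  exceed the initializer's.
* **Seeding.** Every generator is a pure function of its seed. Per-subject
  seeds are the cohort seed plus the subject index, so replicate cohorts in
  Monte-Carlo studies should use master seeds spaced by more than the
  cohort size to keep replicates independent; the package's own validation
  loops space seeds by 40 (imaging cohorts) or 1000 (behavioral cohorts).

## Validation scales

The recovery studies run at sizes chosen to give comfortable Monte-Carlo
margins on a single core: similarity calibration at 20 x 20 items and 5000
voxels (sampling error of the mean pairwise z well under the 0.04 check
band); learning-rate recovery over 500 replicate series; end-to-end link
recovery over 50 replicate 24-subject cohorts at a reduced imaging scale
(4 runs of 8 items, two 80-voxel ROIs) and a 150-replicate null at a
further-reduced scale; and the exclusion-rule scenario (26 subjects,
session noise 148 ms tuned so the expected number of sub-0.7 fits is four)
over 200 replicate cohorts. The real-data effect sizes reported for this
kind of study (r ≈ 0.5 at n ≈ 22) are values from unreleased participant
data and are not reproduction targets; the end-to-end check instead asks
that a preset link of 0.6 is recovered as a positive estimate in at least
90% of replicates and that a zero link is recovered as zero on average.

## Known limitations

Exact GLM recovery on noiseless data is partly by construction, since the
simulator and the design builder share the convolution code; the
convolution itself is therefore checked against an independent direct-sum
oracle, and the similarity and learning estimators are checked against
textbook double-loop and grid-search oracles. The averaged-pattern variant
amplifies the shared component relative to the pairwise mean (item noise
averages out), so the two variants are calibrated differently and should
not be mixed within one analysis. The repeated-measures ANOVA applies no
sphericity correction, matching the analysis it mirrors; with strong
autocorrelated session effects its p-values would be anticonservative.
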