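---
title: "Decoding sensory and perceptual braille letter codes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding sensory and perceptual braille letter codes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braillemvpa)
```

## The question and the measurement logic

When a braille reader identifies a letter, the brain must transform the
tactile input arriving from one particular fingertip into a letter percept
that no longer depends on which hand did the reading. `braillemvpa`
implements the multivariate decoding framework that separates these two
stages in neural pattern data:

* **Within-hand decoding.** A binary classifier is trained and tested on
  responses to two letters read with the *same* hand. Success can rest on
  any letter information — hand-dependent (sensory) or hand-independent
  (perceptual).
* **Across-hand decoding.** The classifier is trained on one hand's
  responses and tested on the other hand's. Only a code that survives the
  change of hand — a perceptual code — can support transfer.
* **Sensory score.** The entrywise difference (within − across) removes the
  transferable part and isolates the hand-dependent code.

Eight letters (B, C, D, L, M, N, V, Z) read with two hands give 16
conditions; all `choose(8, 2) = 28` letter pairs are classified per hand (or
per training-testing direction), and accuracies are averaged over pairs,
folds, iterations and hands. Chance is 50%.

Two additional letters (E, O) serve as rare catch trials requiring a motor
response; they are carried through the containers flagged as `catch` and are
excluded from every analysis.

## The classifier and its cross-validation

The unit classification is a binary soft-margin linear C-SVC (cost
`C = 1`, no feature scaling beyond the noise normalization described below).
Trials of each condition are averaged into 5 pseudo-trials (disjoint random
bins; 170 trials at bin 34, or in general `floor(n/5)` per bin, leftovers
dropped), and a fivefold leave-one-pseudo-trial-out cross-validation trains
on 4 + 4 pseudo-trials and tests on the held-out pair. The binning is
repeated (`n_iterations`, study scale 100) with fresh random assignments and
results averaged, which suppresses binning noise without touching the
train/test separation: bins are disjoint by construction, so no source trial
ever appears on both sides of a fold.

Because the pipeline fits classifiers at every time point × pair × hand ×
fold × iteration × subject (of the order of 10^8 fits in the calibration
studies), the solver is a compact sequential-minimal-optimization routine
specialized for these 8-sample training sets, implemented in C++ with
maximal-violating-pair working-set selection — the same algorithmic family
as libsvm, whose decisions it matches (the test suite compares predictions
and decision values against `e1071::svm` on hundreds of random problems).
The across-hand scheme reuses the within-hand fold skeleton: each trained
model is tested both on the held-out same-hand fold and on the other hand's
corresponding fold, which halves the training work and keeps the two
schemes maximally comparable.

## Preprocessing

* **Baseline correction** subtracts the mean of the 100-ms prestimulus
  window per trial and channel.
* **Multivariate noise normalization** whitens channel patterns by
  `Σ^(-1/2)`, with `Σ` estimated within condition at each time point
  (patterns centered per condition so planted means do not inflate the
  estimate), shrunk toward a scaled identity with the analytic
  (Ledoit–Wolf) intensity, and averaged across time points and conditions.
  We apply the whitening once to the epochs, before binning, as the final
  preprocessing step. An alternative would estimate `Σ` inside every
  cross-validation fold from training data only; since the pooled estimate
  is label-symmetric (it averages over all conditions and time points), it
  cannot inject pair-discriminative structure, and the one-shot variant
  keeps preprocessing strictly upstream of the decoder. With exactly two
  trials per condition the analytic shrinkage intensity degenerates to
  zero (the variance-of-covariance estimate vanishes); a fixed intensity
  can be passed for such corner cases.

## What the synthetic-data generator emulates

The generator exists so that the full pipeline is testable end to end
without any neuroimaging download. It reproduces the *statistical* structure
of the study, not its biophysics (no leadfields, no hemodynamics):

* **Design.** One fMRI run = 80 regular trials (16 conditions × 5) + 5
  catch + 22 null = 107 trials (500-ms stimuli, 2500-ms ISI; null trials
  occupy an empty 3-s slot). One EEG session = 2720 regular (170 per
  condition) + 541 catch = 3261 trials (500/500 ms regular, 1100-ms catch
  ISI). The printed totals are authoritative; the gap rules (a catch every
  ~20 stimulus trials in fMRI, every 5th–7th trial in EEG; nulls after
  every 3rd–5th stimulus trial) are satisfied best-effort, because the
  printed totals and the literal gap distributions are not simultaneously
  satisfiable (541 catch trials in 2720 regulars force a mean gap of ~5.03,
  not 5–7). The realized gap sequence is the exact mix of `floor` and
  `floor+1` gaps that sums to the regular total, shuffled.
* **Two letter codes.** Epochs follow
  `x(t) = noise(t) + [t ≥ t_s]·a_s·P(hand, letter) + [t ≥ t_p]·a_p·Q(letter)`,
  with defaults `t_s = 80 ms`, `t_p = 180 ms`, both codes staying on for
  600 ms. `P` is hand-specific and drives only within-hand decoding; `Q` is
  shared across hands and drives both schemes.
* **Sensory patterns are an orthonormal frame in the decoder's metric.**
  With at least 16 channels, the 16 `P` patterns are drawn as a random
  orthonormal set rather than independent spherical vectors — and the
  frame is made orthonormal *after whitening*: `P = U Σ^(1/2)` with
  orthonormal `U`, so the patterns the classifier actually sees (epochs
  pass through multivariate noise normalization before decoding) are
  exactly orthogonal across hands. Independent spherical draws would leak:
  a chance alignment of order `1/sqrt(n_channels)` between one hand's pair
  contrast and the other hand's patterns is fixed for a subject and, at
  high SNR, becomes decodable, so the "hand-specific" code would no longer
  be hand-specific (we measured subject-level across-hand accuracies up to
  ~63% inside the sensory-only window before adopting the frame). With the
  whitened-metric frame, the only residual transfer comes from whitener
  estimation error, at the fraction-of-a-percent level. Below 16 channels
  orthogonality is impossible and spherical draws are used.
* **Perceptual geometry.** The `Q` patterns realize a planted letter
  dissimilarity, again in the whitened metric. The default geometry is the
  pairwise Hamming distance between the letters' 6-pin braille patterns —
  letters sharing pins are similar — and for this geometry the embedding
  is exact (the centered pin vectors themselves, rotated into channel
  space): squared whitened pattern distance equals pin distance, ties
  included. Arbitrary geometries are embedded by classical MDS of the
  square-rooted dissimilarities and are therefore approximate. Uniform
  scaling preserves rank order, which is all the rank-based RSA uses.
* **Noise.** Gaussian, spatially correlated across channels
  (`Σ_ij = exp(-d_ij/0.04 m)` over a synthetic hemispheric montage),
  white in time by default. Real EEG noise is temporally autocorrelated; an
  AR(1) knob exists for stress tests, with the default kept white so that
  null calibration is exact. Consequences for interpretation: passing
  calibration here shows the pipeline adds no artifactual structure, not
  that it is robust to every property of real recordings (filtering
  artifacts, ICA residues, non-stationarity are out of scope).
* **Ratings.** Participants rate the 28 pairs on a 1–7 integer scale;
  synthetic ratings are a monotone rescaling of the planted geometry plus
  rounded, clipped Gaussian noise. With zero noise the participant-averaged
  rating RDM rank-matches the geometry exactly (the integer scale induces
  ties, but they coincide with the geometry's own ties).

## Statistical inference

Group inference mirrors standard practice for decoding time courses:

* **Wilcoxon signed-rank tests** against chance (50% for accuracies, 0 for
  correlations and difference scores), one-tailed by default (a two-tailed
  option exists). Zeros are handled by the Pratt method; the null
  distribution of the rank sum is computed exactly (valid under ties) for
  up to 25 nonzero differences, with a continuity-corrected normal
  approximation above.
* **FDR control** across time points (or channels × time, or ROIs) by
  Benjamini–Hochberg step-up at `q = 0.05`.
* **Onset latency** is the first post-stimulus time point beginning `k`
  consecutive FDR-significant samples; `k = 50` at the study's 1-ms
  resolution, scaled to `k = 5` on the 10-ms desk grids so the criterion
  spans the same 50 ms.
* **Bootstrap inference.** Subjects are resampled with replacement
  (study scale 1000 resamples); the group trace, its FDR correction and the
  onset are recomputed per resample. Confidence intervals are percentile
  intervals over the defined onsets; resamples without an onset are
  excluded and their fraction reported. The onset *delay* between two
  conditions uses paired resamples and a one-tailed p equal to the
  proportion of resampled differences ≤ 0, BH-corrected when several
  delays are tested at once. Recomputing the FDR inside every resample is
  the statistically coherent choice (reusing the original significance
  mask would understate resampling variability).

## Numerical and design choices

* SVM cost fixed at `C = 1` (the conventional default), exposed but not
  tuned; reproducibility is preferred over per-dataset tuning.
* The sensor searchlight reads "the k closest channels surrounding a
  channel" literally: the center is excluded by default
  (`include_center` flips this). Volumetric spheres include the center,
  with inclusive distance `≤ radius` in voxel units and truncation at grid
  and mask boundaries. 10-ms temporal pooling averages per-sample
  accuracies after decoding, not the data before decoding.
* The sensory RSA curve uses the within-hand RDM (not within-minus-across);
  both are available, and the choice follows the reading that decoding
  accuracies, not difference scores, are sorted into RDMs.
* fMRI pseudo-run binning is done once by default (`n_iterations = 1`),
  with a knob to re-randomize; the EEG path defaults to many iterations.
* Degenerate inputs are first-class: constant RDMs yield an undefined
  Spearman R (reported `NA` with a warning) rather than a fabricated value;
  all-at-chance signed-rank input reports a degenerate test; empty masks,
  non-PD covariances, unbalanced designs and truncated containers raise
  informative errors.
* Desk-scale study conditions used throughout the simulation studies (and
  stated with each result): 16 channels, 20 trials per condition (bins of
  4), 100-Hz sampling over (−100, 390) ms = 50 samples, 10 (calibration) or
  3–5 (effect recovery) pseudo-trial iterations, 11–20 subjects. These
  sizes keep each simulated group in the hundreds of thousands of
  classifier fits while leaving every structural constant (16 conditions,
  28 pairs, 5 folds) at study scale.

## Known limitations

* The generator's effect time courses are step functions; real decoding
  curves rise and decay smoothly, so onset estimators face an easier
  problem here than on empirical data.
* Onset bootstrap CIs are percentile intervals; BCa would need jackknife
  acceleration and was not considered worth the extra machinery at
  n ≤ 20 subjects.
* Volumetric inference stops at a descriptive cluster-forming threshold
  report; no family-wise-error cluster correction is implemented.
* Temporal generalization (train at one time, test at another) is out of
  scope.

## Reproducing the analyses

The `analysis/` directory contains seven numbered drivers (design,
synthesis, time-resolved decoding, ROI decoding, searchlights, RSA, group
statistics) that run the package end to end on one fixed master seed and
write their tables under `results/analysis/`. `run_pipeline()` performs the
same chain as a single call with a hashed output manifest, and
`scripts/acceptance.R` recomputes the pipeline's chance-level calibration
from scratch for any seed.
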