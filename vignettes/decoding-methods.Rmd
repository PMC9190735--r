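---
title: "Time-resolved multivariate decoding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-resolved multivariate decoding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpatime)
```

# Overview

`mvpatime` implements a complete time-resolved multivariate pattern
analysis (MVPA) pipeline for epoched multichannel recordings such as EEG:
a synthetic-data generator with planted representational dynamics,
automated artifact rejection and anti-aliased downsampling, super-trial
(pseudo-trial) averaging with multivariate noise normalization, pairwise
linear SVM decoding at every timepoint — within one modality, across
modalities, and over the full train-time × test-time generalization grid —
and group-level nonparametric inference (sign-flip cluster-size
permutation tests and a participant-bootstrap comparison of peak
latencies). Every stage is seeded and reproducible; `runPipeline()`
orchestrates an end-to-end run from a single YAML configuration.

The canonical experiment the defaults describe is a two-modality
object-categorization session: 48 object conditions crossed with three
orthogonal binary category dimensions (size, movement, naturalness; 24
objects on each side of every division), 8 auditory and 6 visual runs of
300 trials each (5 presentations of each stimulus per run plus 20%
one-back repetition trials), 63-channel recordings epoched from −200 to
800 ms around stimulus onset, acquired at 1000 Hz and analyzed at 200 Hz.

# The decoding model

## Super-trials

Single trials are noisy; decoding operates on **super-trials**, averages
of randomly partitioned subsets of same-condition trials.

* **Object scheme** (`makeObjectSupertrials()`): per object, trials are
  randomly split into 3 near-equal groups and averaged. All object pairs
  are classified with leave-one-super-trial-out cross-validation (train
  on 2, test on 1, all 3 folds).
* **Category scheme** (`makeCategorySupertrials()`): trials are first
  averaged per object; within each level of one category dimension the
  *object averages* are randomly split into 3 groups and averaged.
  Because each object enters exactly one super-trial (asserted through
  the recorded provenance), training and testing never share an object,
  so above-chance accuracy reflects category structure that generalizes
  across objects rather than the identity of individual stimuli. A
  stricter leave-one-object-out variant (`leaveOneObjectOutDecode()`)
  trains on all object averages but one and tests on the held-out
  object.

The random partition is regenerated on every repetition (100 in the
full-scale scheme; reduced in the demo configuration) and accuracies are
averaged over folds, pairs, repetitions and — for the category measure —
over the three dimensions. When trial counts are not divisible by the
group count the remainders are assigned to randomly chosen groups, which
keeps group sizes within one trial of each other without bias.

## Multivariate noise normalization

`fitNoiseNormalizer()` whitens sensor patterns so channels (and channel
combinations) with high noise covariance are down-weighted. At every
timepoint the within-condition residual covariance is estimated from
single trials and regularized by analytic Ledoit–Wolf shrinkage toward a
scaled identity, \eqn{\hat\Sigma_t = \lambda m I + (1-\lambda) S_t}; the
per-timepoint estimates are averaged over the epoch and the whitening
transform is \eqn{W = \bar\Sigma^{-1/2}} (symmetric matrix square root).
Three choices here were genuinely open and are resolved as follows:

* the covariance is fit on **single-trial** residuals (many more degrees
  of freedom) and applied to the super-trials that enter classification;
* one **epoch-average** transform is used rather than a time-resolved
  one — time-resolved whitening at 3 super-trials per condition is far
  too noisy;
* the **same normalizer** is used for the object and category schemes of
  a participant/modality.

A `normalized` flag on the super-trial container guards against double
whitening, which would silently distort patterns.

## The classifier

All schemes use a soft-margin linear SVM with the cost fixed at `c = 1`
and no feature scaling beyond noise normalization; features are the
channel pattern at a single timepoint. Training sets are tiny (4 points
for a pairwise fold), so the dual problem is solved exactly by a
maximal-violating-pair SMO implemented in compiled code
(`src/decode_core.cpp`), with the offset taken as the midpoint of the
KKT interval of the final dual solution. The test suite verifies on
hundreds of random problems that the solver attains the libsvm (e1071)
optimum, and checks fold accuracies against a brute-force geometric
maximum-margin oracle on 2-points-per-class problems. Classification is
performed at every sample of the analysis time axis (5 ms steps at
200 Hz).

## Cross-modal decoding and temporal generalization

`crossmodalDecode()` trains on all category super-trials of one modality
and tests on all of the other (no folds), at the same timepoint;
`temporalGeneralization()` does the same for every train × test timepoint
pair. Both average the two train/test directions, the three category
dimensions, and the repartition repetitions. Cross-modal analyses operate
on category-level (object-average based) super-trials; an object-level
variant is available through the same machinery but is not the default.

# Group inference

## Sign-flip cluster-size permutation test

`clusterPermutationTest()` centers participant time courses on the 50%
chance level and computes a one-sided pointwise group statistic (the
group mean by default; a one-sample *t* is available — under the
symmetric null both are valid sign-flip statistics). The null is built
from random ±1 multiplications of each participant's centered time
course (10,000 by default, the identity assignment always included, so
p ≥ 1/nPermutations and p = 0 is impossible; an exhaustive mode
enumerates all 2^n assignments for small groups). Timepoints exceeding
the pointwise (1 − α) null quantile form contiguous candidate clusters
scored by **size** (number of supra-threshold timepoints); cluster
significance is assessed against the null distribution of the maximum
cluster size, which controls the family-wise error over timepoints. Both
the cluster-forming and the cluster-level threshold are 0.05, one-sided.

## Bootstrap peak-latency comparison

`bootstrapPeakLatencyDifference()` resamples participants with
replacement (1,000 samples; the same resample applied to both
conditions), recomputes the group-mean time courses, and records the
latency of each maximum. The one-tailed p value is the fraction of
bootstrap samples whose latency difference lies strictly on the
hypothesized side. Ties in the maximum are broken to the earliest
timepoint, and flat curves (or an all-zero difference distribution, as
when both inputs are identical) are flagged as degenerate rather than
rejected.

# The synthetic-data generator

No recorded EEG ships with the package; `simulateEpochs()` generates
epochs with planted dynamics so that every claim the pipeline makes can
be verified against known ground truth. A trial of object *o* in
modality *m* is

$$ x(t) = \mathrm{snr}\cdot M_m\Big[p_o\,e_{obj}(t) +
   \sum_d c_{d,l_d(o)}\,e_{cat}(t)\Big] + \varepsilon(t),
   \qquad \varepsilon(t) \sim N(0, \Sigma), $$

with independent unit-norm Gaussian channel patterns \eqn{p_o} (one per
object) and \eqn{c_{d,l}} (one per category level and dimension),
envelopes \eqn{e(t)} that are 0 before the respective onset and ramp
linearly to 1 over 20 ms (the ramp avoids ringing in onset-recovery
checks; 0 gives a hard step), and stationary channel noise
\eqn{\Sigma_{ij} = \sigma^2 \rho^{|i-j|}} (ρ = 0.3, σ = 1 by default),
white across time. Default onsets plant the object code at 75 ms and the
category code at 305 ms. The modality codes \eqn{M_m} are either shared
(identity: one modality-independent pattern basis, so cross-modal
decoding succeeds) or — the default — projections onto orthogonal halves
of a random orthonormal channel basis, in which case the two modalities'
realized sensor patterns are exactly orthogonal and cross-modal decoding
stays at chance. Each simulated participant receives independently drawn
patterns; effects align across participants only in time, which is what
the group statistics operate on.

What the generator deliberately does **not** emulate: temporal
autocorrelation and non-stationarity of real EEG noise, volume-conducted
spatial structure beyond the exponential correlation, eye/muscle
artifacts (the artifact-rejection stage is exercised with injected
amplitude spikes instead), inter-trial intervals and stimulus durations
(epochs are generated directly; no analysis stage consumes the
inter-trial structure), and any systematic relation between an object's
pattern and its category patterns. Passing tests therefore demonstrate
the correctness and calibration of the *pipeline*, not that real EEG
carries these codes.

Trial sequences do emulate the behavioral task structure: per run every
stimulus appears exactly `repsPerStimPerRun` times in pseudorandom order
with no accidental immediate repeats, and one-back repetition trials
(an immediate flagged repeat, never two in a row) are inserted at
uniformly random eligible positions until they make up 20% of the run.
One-back trials are excluded before artifact rejection.

# Preprocessing

* **Artifact rejection** (`rejectArtifacts()`): per trial and channel,
  the epoch-summed absolute deviation from the across-trial channel mean
  is z-scored per channel across trials; a trial is removed when its
  maximum over channels exceeds 20. The z-metric is bounded by roughly
  √n, so the default threshold only bites in realistically large
  sessions (hundreds of trials) — intentional for a jump-artifact
  detector. A warning fires when more than 10% of trials are removed.
* **Downsampling** (`downsampleEpochs()`): integer decimation with a
  zero-phase (forward–backward) order-4 Butterworth low-pass at 80% of
  the target Nyquist, applied with reflection padding to suppress edge
  transients, implemented as a precomputed linear operator for speed.
  1000 Hz → 200 Hz turns the −200…800 ms epoch into 201 samples at 5 ms
  spacing.

# Numerical and design choices

* **Seeds**: every stochastic stage takes a seed; nested stages derive
  child seeds deterministically from the global one, so a pipeline run
  is bit-reproducible from its manifest. All stages run serially; the
  per-stage child-seed scheme guarantees that any future concurrent
  evaluation of repetitions or pairs would reproduce the serial results.
* **SVM**: dual tolerance 1e−9, exact for these problem sizes; decision
  values of exactly 0 count as errors for both classes (they occur with
  probability 0 on continuous data).
* **Cluster test**: per-timepoint critical values are type-1 empirical
  quantiles of the sign-flip null; cluster p values use ≥ on the
  max-size null and significance uses p < α.
* **Whitening**: eigendecomposition-based inverse square root; the
  shrinkage intensity is clipped to [0, 1] and reported.
* **Degenerate inputs**: flat decoding curves tie-break peaks to the
  earliest timepoint and set a `degenerate` flag; identical conditions
  in the peak test force p = 0 under the strict ">" counting rule and
  are flagged rather than hidden.

# Problem sizes in the shipped tests

The test-suite and the calibration script run the pipeline at desk
scale, chosen so the full suite completes in a few minutes while keeping
every statistical check well-powered: typically 8–48 objects, 10–63
channels, 200 Hz analysis axis (201 timepoints; 50 Hz for the
generalization grid), 6–20 simulated participants, 2–10 super-trial
repetitions, 1,000–10,000 permutations and 1,000 bootstraps. The
calibration script (`scripts/acceptance.R`) recomputes the two headline
quantities — the chance-level grand mean of signal-free object decoding
(12 participants) and the family-wise false-positive rate of the cluster
test (200 null datasets) — from scratch at every invocation.

# Known limitations

* The generator's white-in-time epoch noise makes onset recovery
  slightly sharper than real, autocorrelated EEG would allow; the
  cluster test's error rate is therefore additionally calibrated on
  AR(1) accuracy noise (`simulateNullAccuracies()`).
* The epoch container serializes to R-native RDS; there is no reader
  for vendor EEG formats — the pipeline starts from epoched arrays.
* Cluster inference is cluster-*size* based; mass-based or
  threshold-free variants are out of scope.
* Accuracies from the object and category schemes are not directly
  comparable (different numbers of training exemplars and averaging
  depths); compare latencies and significance patterns, not absolute
  percent correct.
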