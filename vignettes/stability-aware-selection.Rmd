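---
title: "Stability-aware feature selection for small-sample movement classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-aware feature selection for small-sample movement classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Case-control studies of movement — for instance, comparing autistic and
non-autistic adults on a movement imitation task — routinely produce data
sets with far more features than participants: a few dozen people, but
hundreds of derived kinematic and eye-movement summaries. Two failure modes
dominate such analyses. First, performance estimates are optimistic when any
part of model development (normalisation, feature selection, hyperparameter
tuning) sees the validation data. Second, feature selection is unstable:
re-running a selector on a slightly different subsample returns a different
feature set, which destroys interpretability even when accuracy is
unchanged.

`stabselect` implements a development-and-testing stack built around both
concerns: leakage-free nested cross-validation with independent-sample
testing, and selection methods whose explicit objective is stability,
measured by Kuncheva's index. A synthetic cohort generator with planted,
known group effects makes every stage testable without access to human
data.

## The data model

A `feature_matrix` holds samples × features with two-class labels and
per-feature metadata (modality, block, condition, base measure, statistic).
The canonical layout mirrors a two-block (general-instruction /
attention-instruction), three-condition (direct, elevated, direct-fast)
imitation experiment:

* **Kinematic features** — 20 per-trial base measures (velocity,
  acceleration, deceleration and jerk peaks and their timings as % of
  movement duration, amplitudes, path geometry, movement duration), each
  summarised per participant × condition by the mean and SD over trials:
  20 × 2 × 3 = 120 features per block.
* **Eye features** — 8 per-trial measures from pre-parsed saccade and
  fixation events (count, amplitude, duration, peak velocity, first-saccade
  latency, fixation duration, % dwell on the finger, gaze-finger distance):
  8 × 2 × 3 = 48 features per block.

The measure lists are this package's canonical decomposition; published
figure panels describing the original feature inventories are not machine
readable, so the 20- and 8-measure sets were fixed once to reproduce the
documented totals (120 and 48 per block) and to include every measure named
in the accompanying text (vertical amplitude, acceleration/deceleration
timing percentages, dwell on the finger).

## Preprocessing

* **Trial-level outliers** are trimmed with the non-recursive,
  sample-size-dependent criterion of Van Selst & Jolicoeur (1994): values
  farther than C(n)·SD from the participant-condition mean are removed,
  with C interpolated from the published table (1.458 at n = 4 up to 2.50
  at n ≥ 100). Below four observations nothing is removed. The procedure is
  single-pass.
* **Gaze screening** drops trials whose missing-data fraction exceeds 1/3
  (strictly; exactly 1/3 is retained).
* **Group-level outliers and missing cells** are replaced with per-group
  means of the non-outlying observations. On the independent test set, the
  *development-set* group means are used, so test-set labels never
  influence test-set values; a strict mode uses pooled label-free means for
  sensitivity analysis.
* **z-scoring** is fitted on training rows only (unbiased SD; constant
  features get divisor 1) and applied to validation/test rows inside every
  fold — the normalisation never sees held-out data.

## Classification and evaluation

The classifier is an RBF-kernel SVM. Hyperparameters are grid-searched over
C = 2^j (j = 1…7) and γ = 2^i (i = −1…−7) by stratified inner 10-fold CV;
accuracy ties resolve to the smallest C, then the largest γ (the smoother
model). Development uses 10 stratified outer folds: normalisation, selection
and tuning are re-fitted inside each fold and the untouched fold scored; the
development accuracy is the mean of the ten fold accuracies. The ten fitted
fold models are then applied to the independent test sample and their
accuracy/sensitivity/specificity averaged (positive class = autistic).
Fifty repeated runs with fresh partitions give performance distributions.
Statistical significance uses label permutation: the whole pipeline
(selection included) is rerun per permutation and
p = (#{permuted ≥ observed} + 1)/(n_perm + 1), so 100 permutations floor at
p = 1/101.

Permutations are drawn within the development set and within the test set
rather than across their union: stratified 10-fold partitions (and the 50%
chance level assumed by the wrapped selector's update rule) require each
set to remain balanced, which a pooled permutation of 44 labels does not
guarantee at these sample sizes.

## Feature selection

Four base rankers (all returning a full ordering, deterministic up to the
documented tie-breaks: primary score, then |t|, then feature id):

* `t_rank` — descending absolute pooled-variance two-sample t.
* `svm_rfe_rank` — recursive elimination by linear-SVM weight magnitude,
  dropping 10% of remaining features per iteration (step size 1 available
  for auditing).
* `relieff_rank` — nearest hit/miss feature weighting (Manhattan distance
  on range-normalised features, k = 10 neighbours clipped to class size).
* `mrmr_rank` — greedy MID (relevance minus mean redundancy) on mutual
  information after 3-bin mean ± SD discretisation; MIQ available.

Three stability-oriented methods build on these:

* **Ensemble** — Borda aggregation (sum of the four rank positions) with
  the top k kept.
* **t-test with bagging** — the t ranking run on 100 stratified half-size
  subsamples; the k most frequently selected features win (frequency ties
  by mean |t| across bags).
* **Wrapped t-test** — the package's core method. Per-feature ranking
  scores start at |t| and accumulate small adjustments: in each iteration,
  each of the 10 frozen folds selects its top-k by adjusted score, trains
  an SVM (fixed C = 4, γ = 2⁻⁴ inside the loop; tuning every iteration
  would be computationally prohibitive and the final reported models are
  tuned by the evaluation engine anyway) and scores its held-out fold.
  Fold accuracy above 50% adds δ to the selected features' adjustments,
  below 50% subtracts δ, exactly 50% leaves them unchanged; updates apply
  fold-sequentially within an iteration. The run terminates once
  Kuncheva's index over the ten fold selections has been exactly 1 for 100
  consecutive iterations, returning the single common set. The default
  δ = 0.0001 converges within the documented 100,000-iteration cap;
  δ = 0.01 is a faster setting used throughout the test suite. The fold
  partition is frozen per run so the index measures selection stability,
  not partition noise. A non-convergent run raises a typed condition
  carrying the full state (adjustments, fold accuracies, per-iteration
  selections), and `replay_adjustments()` re-executes the update rule from
  that log for auditing.

When the wrapped selector is evaluated, the evaluation engine mirrors the
method's published structure: the wrapped run's own frozen fold partition
*is* the outer cross-validation partition. The selection loop runs once on
the development set; at termination every fold selects the identical
common set, each fold's SVM is then grid-searched on that set and scored
on its held-out fold, and those ten tuned fold models are the ones carried
to independent testing. (Re-running the whole wrapped procedure inside
every fold of a second cross-validation level would square the cost and
evaluate a different algorithm than the one described.)

Stability is quantified by Kuncheva's index: the mean over subset pairs of
(|Sᵢ∩Sⱼ|·l − k²)/(k(l−k)), which is 1 only for identical subsets, has
expectation 0 for random ones, and reaches −1 for disjoint half-universe
subsets. The printed summation bounds in the original equation are treated
as a typo for the standard all-pairs i<j sum — the 2/(m(m−1)) prefactor is
exactly the all-pairs normaliser.

All selectors return exactly k features; k defaults to 10, the
approximately optimal feature count for training samples of this size.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes — it
is a first-class module, not a test fixture.

**Trial path.** Each participant contributes `trials_per_condition` trials
per condition per block. The longitudinal profile is a beta-family bell
velocity, v(τ) ∝ τ^p(1−τ)^q over 0.15 m; p = q = 2 is exactly the
minimum-jerk profile, and the exponents provide analytically tractable
control over acceleration/deceleration peak timing. The vertical component
is a parabolic arc (height per condition: 2.5/8.5/2.0 cm for
direct/elevated/direct-fast; durations 0.60/0.70/0.38 s), sampled at
120 Hz with 0.5 mm measurement noise. Parameters follow a two-level
hierarchy (between-participant and trial-level Gaussians; e.g. duration
0.05/0.03 s, height 12/6 mm); autistic trial-level SDs are multiplied by
`variability_inflation` (default 1.3), reflecting the broadly higher
movement variability reported in autistic cohorts — the package does not
target an exact percentage of elevated variability features. Gaze trials
carry pre-parsed saccade/fixation events from the same hierarchy, and a
configurable fraction of trials (default 0.15) receives a missing-data
fraction uniform on [0, 0.6].

Group effects are *planted* as (feature id, Cohen's d) pairs, d signed
autistic-minus-non-autistic. The default set plants ten features with |d|
in 0.75–0.93 concentrated in the elevated condition of the general block
(lower vertical amplitude, earlier peak acceleration, later peak
deceleration, longer durations, reduced dwell on the finger), matching the
magnitudes and direction pattern of published group statistics for this
task. The mean shift for a planted feature equals d times the pooled SD of
the extracted participant-level feature implied by the hierarchy (including
the variability inflation and averaging over trials); for the timing
percentages, shifts in (p, q) are solved through a numerically computed
2×2 Jacobian of the peak timings. Only measures with a direct generator
parameter are plantable on the trial path (vertical amplitude, duration,
the two timing percentages, and all non-count eye measures); other ids
raise an error. Monte-Carlo recovery of the realized d is part of the test
suite.

**Matrix path.** `generate_feature_matrix()` samples the 168-column block
directly: one latent factor per modality with loading √r yields mean
pairwise within-modality correlation r (defaults 0.20 kinematic, 0.48
eye — eye features are substantially more inter-correlated); planted
effects shift the autistic mean by exactly d on the standardised scale, and
the variability inflation appears as a 0.5·(v−1) SD shift on SD-statistic
columns. Development and test matrices are two draws from the same
population. Because cross-modality correlation is zero under the
per-modality factor model, the combined-set mean correlation (~0.14) falls
slightly below the per-modality targets; only the per-modality means are
calibrated.

**What the generator does not emulate:** raw eye-tracker sample streams,
pupil signals, video stimuli, non-Gaussian heavy tails, block-order
(learning) effects, or realistic missingness mechanisms (missingness is
independent of the data). Passing tests therefore demonstrate the
correctness and calibration of the pipeline, not classifiability of any
real population.

## Numerical and design choices

* A "120 Hz Butterworth filter" at a 120 Hz sampling rate is not a
  realizable low-pass cutoff; trajectories are filtered with a 4th-order
  zero-phase low-pass at 10 Hz (configurable), the conventional choice for
  reaching movements. Zero-phase filtering uses odd-reflection end padding
  so ramp-like trajectories pass without edge transients; the effective
  gain is the squared single-pass Butterworth gain.
* Derivatives are central differences on filtered positions, one-sided at
  the endpoints. The longitudinal axis is the start→end chord; peak
  deceleration is reported as the magnitude of the most negative
  longitudinal acceleration; vertical amplitude is the z-range.
* Whether the wrapped adjustments apply per fold or once per iteration is
  ambiguous in prose descriptions of such schemes; this implementation
  updates fold-sequentially within an iteration (each fold sees the
  adjustments accumulated by the folds before it), which is deterministic
  and matches the per-fold reading.
* Ensemble voting is Borda (rank-sum); plurality-of-top-k is a coarser
  alternative that discards most of each ranking.
* Fewer than 4 observations: outlier trimming passes data through
  unchanged. Constant features: z-score divisor 1; mRMR discretisation
  maps them to a single bin (zero relevance); ReliefF range-normalisation
  treats them as zero-contribution.

### Test fixture sizes and signal strengths

The suite runs entirely on synthetic cohorts at the study's sample sizes
(15+15 development, 7+7 test). Two deliberate fixture choices:

* The wrapped-selector *recovery* fixture plants |d| = 1.4 (same features
  and sign pattern as the defaults). At the study effect sizes
  (|d| ≤ 0.93) and n = 30, the 10-feature support is not statistically
  identifiable — among 158 null features the expected number with |t|
  above a d = 0.9 feature's is about eight — so a recovery criterion at
  those magnitudes would measure ranking noise rather than algorithm
  correctness. Weakly identifiable signals can also hold the wrapped
  selector in parallel escalation (different folds boosting different
  sets indefinitely), which the iteration cap converts into a typed
  error. The agreement between development and testing accuracy *is*
  checked at the published effect sizes.
* Monte-Carlo checks of the trial-path planting use 40 replicates with 6
  trials per condition (standard error of the mean realized d ≈ 0.05,
  well inside the ±0.25 acceptance band); development/testing agreement
  uses 20 seeds × 5 repeated partitions, because single-partition accuracy
  estimates at n = 30 carry ~0.1 sampling SD.

## Known limitations

* The wrapped t-test's convergence is not guaranteed; symmetric fold
  preferences can escalate in parallel. The iteration cap plus the typed
  error state is the designed failure mode.
* Group-mean imputation uses class labels (as is standard for this
  analysis family); although the test set is imputed with development
  means, development-set imputation itself is mildly label-aware and can
  shrink within-group variance. The strict pooled mode quantifies this.
* Trial-path planting propagates through extraction (filtering,
  differentiation, event averaging), so realized effect sizes carry small
  attenuation/amplification relative to the nominal d; the matrix path is
  exact by construction.
* SVM-RFE uses a linear kernel for its weight criterion even though the
  final classifier is RBF; this follows the method's original formulation.
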