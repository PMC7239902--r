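# stabselect

Stability-aware feature selection and leakage-free evaluation for
small-sample, high-dimensional movement classification.

## The problem

Case-control movement studies — for example, distinguishing autistic from
non-autistic adults using kinematic and eye-tracking summaries of a
movement imitation task — typically have a few dozen participants and
hundreds of features. Two things go wrong in that regime:

1. **Optimistic accuracy.** If normalisation, feature selection or
   hyperparameter tuning ever touches the validation data, cross-validated
   accuracy overstates how well the model generalises.
2. **Unstable feature selection.** Rerunning a selector on a slightly
   different subsample returns a different feature set, which makes the
   selected features uninterpretable as markers even when accuracy is
   unchanged.

`stabselect` packages a pipeline that addresses both: nested
cross-validation (normalisation, selection and tuning re-fitted inside
every outer fold), independent-sample testing by averaging the ten fold
models, permutation significance for the whole pipeline, and selection
methods whose explicit objective is *stability*.

## The core methods

**Kuncheva's stability index.** For `m` feature subsets S₁…Sₘ, each of
size `k` drawn from `l` features, the chance-corrected similarity

    KI = 2 / (m(m-1)) · Σ_{i<j} (|Sᵢ ∩ Sⱼ|·l − k²) / (k(l−k))

equals 1 only when all subsets are identical, has expectation 0 for random
subsets, and reaches −1 for disjoint subsets with k = l/2.

**Wrapped t-test selection.** A hybrid of filter and wrapper selection
driven by stability. Features are ranked by |t| (two-sample, pooled
variance) plus an accumulated per-feature adjustment. Per iteration, each
of 10 frozen CV folds selects its top-k by adjusted score, trains an
SVM-RBF on them and scores its held-out fold; fold accuracy above 50%
(chance for balanced classes) adds δ to the selected features'
adjustments, below 50% subtracts δ. The run stops when all ten folds have
selected the identical set (KI = 1) for 100 consecutive iterations and
returns that single common set — one consistent, interpretable feature
set, with the full adjustment/accuracy/KI trajectory logged and
replayable.

Also included: t-test, SVM-RFE, ReliefF and mRMR rankers; Borda-ensemble
selection; t-test with bagging (stability selection on 100 half-size
subsamples); Van Selst–Jolicoeur sample-size-dependent outlier trimming;
group-mean imputation with development-derived parameters for the test
set; a 120-feature-per-block kinematic and 48-feature-per-block eye
feature extractor; and a synthetic cohort generator with planted,
known-magnitude group effects for end-to-end validation.

## Worked example

Simulate a cohort with the default planted effects (10 features at
|d| = 0.75–0.93, concentrated in the elevated condition), then develop and
test a classifier with t-test selection:

```r
library(stabselect)

spec <- cohort_spec()                       # 15+15 development, 7+7 test
mats <- generate_cohort_matrices(spec, blocks = "general", seed = 2)
sel  <- make_selector("ttest", k = 10)
res  <- repeat_runs(mats$dev, mats$test, sel, classifier_config(),
                    n_repeats = 5, seed = 2)
print(res)
#> <evaluation_result> 5 repeats
#>     metric median    q1    q3  mean
#>    dev_acc  0.875 0.850 0.875 0.865
#>         ki  0.721 0.688 0.733 0.707
#>   test_acc  0.829 0.807 0.829 0.816
#>  test_sens  0.871 0.857 0.886 0.874
#>  test_spec  0.743 0.729 0.786 0.757
```

Development accuracy (mean of ten outer-fold accuracies, re-selecting
features inside every fold) agrees with the accuracy of the same ten
models on the untouched 7+7 test sample — the signature of a leakage-free
pipeline. `ki` is the stability of the ten fold-wise selections.

The wrapped t-test yields a single stable set (here with δ = 0.01 for
speed; the conservative default is 0.0001):

```r
z  <- apply_zscore(fit_zscore(mats$dev), mats$dev$values)
wr <- wrapped_t_select(z, mats$dev$labels, k = 10, delta = 0.01, seed = 2)
wr$state$iterations
#> [1] 131
head(wr$features, 3)
#> [1] "eye.general.direct_fast.saccade_count.SD"
#> [2] "eye.general.direct.fixation_duration.mean"
#> [3] "eye.general.direct.saccade_amplitude.mean"
```

Significance of the result against label permutation (the entire pipeline
is rerun per permutation; with 100 permutations the smallest attainable
p is 1/101):

```r
pt <- permutation_significance(mats$dev, mats$test, sel,
                               classifier_config(C = 4, gamma = 2^-4),
                               n_perm = 100, seed = 2)
pt$p
#> [1] 0.00990099
```

A full simulate → extract → preprocess → select → evaluate run, with
per-stage artifacts (feature CSVs, selection and results JSON, report),
is available as `run_pipeline(run_config(...), out_dir)`, or from the
shell via the thin dispatcher `inst/cli/stabselect`.

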