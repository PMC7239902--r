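test_that("cohort specification validates its inputs", {
  expect_s3_class(cohort_spec(), "cohort_spec")
  expect_error(cohort_spec(n_per_group_dev = 0))
  expect_error(cohort_spec(mean_corr_eye = 1))
  expect_error(cohort_spec(planted_features = data.frame(
    feature_id = "kinematic.general.elevated.bogus.mean", d = 1)),
    "unknown feature id")
  expect_error(cohort_spec(planted_features = data.frame(
    feature_id = rep(default_planted_features()$feature_id[1], 2),
    d = c(1, 2))), "duplicate")
  expect_error(cohort_spec(planted_features = data.frame(
    feature_id = default_planted_features()$feature_id[1], d = Inf)),
    "finite")
})

test_that("trial generation covers every participant, block and condition", {
  spec <- cohort_spec(n_per_group_dev = 3, n_per_group_test = 2,
                      trials_per_condition = 3)
  sim <- generate_trials(spec, seed = 4)
  expect_equal(nrow(sim$participants), 2 * (3 + 2))
  counts <- table(sim$participants$set) / 2
  expect_equal(as.vector(counts[c("dev", "test")]), c(3, 2))
  key <- unique(sim$movement[, c("participant", "block", "condition", "trial")])
  expect_equal(nrow(key), 10 * 2 * 3 * 3)   # participants x blocks x conds x trials
  # timestamps: strictly increasing at nominal 1/120 s
  one <- subset(sim$movement, participant == key$participant[1] &
                  block == key$block[1] & condition == key$condition[1] &
                  trial == key$trial[1])
  expect_true(all(abs(diff(one$t) - 1 / 120) < 1e-12))
  # start and end approximately 0.15 m apart along the movement axis
  expect_equal(one$x[nrow(one)] - one$x[1], 0.15, tolerance = 0.01)
  # gaze: missing fractions within [0, 1], event onsets within trial
  expect_true(all(sim$gaze$missing_fraction >= 0 &
                    sim$gaze$missing_fraction <= 1))
  expect_true(all(sim$gaze$onset >= 0))
  # planting on a measure with no generator parameter errors
  bad <- cohort_spec(planted_features = data.frame(
    feature_id = "kinematic.general.direct.peak_jerk.mean", d = 0.9))
  expect_error(generate_trials(bad, seed = 1), "without a generator parameter")
})

test_that("seeded generation is bit-reproducible", {
  spec <- cohort_spec(n_per_group_dev = 2, n_per_group_test = 1,
                      trials_per_condition = 2, blocks = "general")
  expect_identical(generate_trials(spec, seed = 99),
                   generate_trials(spec, seed = 99))
  expect_identical(generate_feature_matrix(spec, seed = 5)$values,
                   generate_feature_matrix(spec, seed = 5)$values)
})

test_that("null cohorts have exchangeable groups on extracted features", {
  spec <- cohort_spec(n_per_group_dev = 11, n_per_group_test = 0,
                      trials_per_condition = 6, planted_features = NULL,
                      variability_inflation = 1, blocks = "general")
  pvals <- c()
  for (s in 1:8) {
    sim <- generate_trials(spec, seed = 500 + s)
    kin <- extract_kinematic_features(sim$movement, "general")
    tt <- stabselect:::pooled_t(kin$values, kin$labels)
    df <- 2 * 11 - 2
    pvals <- c(pvals, 2 * pt(-abs(tt), df))
  }
  # two-sample t on extracted features rejects at about the nominal rate
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.025)
  expect_lt(rate, 0.075)
  # marginal distributions indistinguishable between groups at large n
  big <- generate_feature_matrix(
    cohort_spec(planted_features = NULL, variability_inflation = 1),
    n_per_group = 400, seed = 17)
  ks <- ks.test(big$values[big$labels == "autistic", 1],
                big$values[big$labels != "autistic", 1])
  expect_gt(ks$p.value, 0.01)
})

test_that("trial-path planting is recovered in extracted features (Monte-Carlo)", {
  pl <- default_planted_features()
  spec <- cohort_spec(trials_per_condition = 6, blocks = "general")
  target <- "kinematic.general.elevated.vertical_amplitude.mean"
  n_rep <- 40
  ds <- matrix(NA_real_, n_rep, nrow(pl), dimnames = list(NULL, pl$feature_id))
  for (r in seq_len(n_rep)) {
    sim <- generate_trials(spec, seed = 3000 + r)
    kin <- extract_kinematic_features(sim$movement, "general")
    eye <- aggregate_eye_features(
      screen_missing_gaze(sim$gaze), "general",
      participants = sim$participants[, c("participant", "group")])
    fm <- impute_group_outliers_and_missing(combine_features(kin, eye))
    for (j in seq_len(nrow(pl))) {
      ds[r, j] <- cohens_d(fm$values[, pl$feature_id[j]], fm$labels)
    }
  }
  realized <- colMeans(ds)
  # headline check: d = -0.93 on the elevated vertical-amplitude mean,
  # pooled development + test sample (22 + 22)
  expect_equal(unname(realized[target]), -0.93, tolerance = 0.25)
  # every planted feature lands near its specified effect size
  expect_true(all(abs(realized - pl$d) < 0.25))
})

test_that("matrix-path planting and correlation targets are exact at scale", {
  spec <- cohort_spec()
  # realized d converges to specified d (20 draws at n = 500/group)
  pl <- default_planted_features()
  dsum <- 0
  for (r in 1:20) {
    fm <- generate_feature_matrix(spec, n_per_group = 500, seed = 700 + r)
    dsum <- dsum + vapply(pl$feature_id, function(f)
      cohens_d(fm$values[, f], fm$labels), 0)
  }
  expect_true(all(abs(dsum / 20 - pl$d) < 0.05))

  # mean absolute off-diagonal correlation of eye columns near 0.48
  fm <- generate_feature_matrix(cohort_spec(planted_features = NULL),
                                n_per_group = 500, seed = 88)
  eye_cols <- fm$feature_meta$modality == "eye"
  cc <- cor(fm$values[, eye_cols])
  expect_equal(mean(abs(cc[upper.tri(cc)])), 0.48, tolerance = 0.07)
  kin_cols <- fm$feature_meta$modality == "kinematic"
  ck <- cor(fm$values[, kin_cols])
  expect_equal(mean(abs(ck[upper.tri(ck)])), 0.20, tolerance = 0.05)

  # zero correlations, zero effects: columns behave independently
  fm0 <- generate_feature_matrix(
    cohort_spec(planted_features = NULL, mean_corr_kinematic = 0,
                mean_corr_eye = 0, variability_inflation = 1),
    n_per_group = 1000, seed = 3)
  c0 <- cor(fm0$values[, 1:40])
  expect_lt(max(abs(c0[upper.tri(c0)])), 4.5 / sqrt(2000))

  # a planted 10-feature signal has the 10 largest population |t| values
  fm_big <- generate_feature_matrix(spec, n_per_group = 2500, seed = 44)
  tt <- abs(stabselect:::pooled_t(fm_big$values, fm_big$labels))
  # exclude the SD-statistic columns, which carry the variability shift
  mean_cols <- fm_big$feature_meta$statistic == "mean"
  top10 <- names(sort(tt[mean_cols], decreasing = TRUE))[1:10]
  expect_setequal(top10, pl$feature_id)
})

test_that("trial and gaze tables round-trip through TSV", {
  spec <- cohort_spec(n_per_group_dev = 2, n_per_group_test = 0,
                      trials_per_condition = 2, blocks = "general")
  sim <- generate_trials(spec, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trials_tsv(sim$movement, path)
  back <- read_trials_tsv(path)
  expect_equal(back$x, sim$movement$x, tolerance = 1e-9)
  expect_equal(back$participant, sim$movement$participant)
})
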