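test_that("the default grids span C in [2, 128] and gamma in [2^-7, 2^-1]", {
  cfg <- classifier_config()
  expect_equal(cfg$C, 2^(1:7))
  expect_equal(cfg$gamma, 2^(-(1:7)))
  expect_equal(cfg$inner_folds, 10)
  expect_equal(range(cfg$C), c(2, 128))
  expect_equal(range(cfg$gamma), c(2^-7, 2^-1))
  expect_error(classifier_config(C = numeric(0)))
  expect_error(classifier_config(C = -1))
})

test_that("grid search returns a single-point grid directly and matches a brute-force oracle", {
  fm <- tiny_fm(n_per_group = 10, p = 5, seed = 3, d = 2)
  z <- apply_zscore(fit_zscore(fm), fm$values)
  single <- grid_search_svm(z, fm$labels, classifier_config(C = 4, gamma = 0.25))
  expect_equal(single$C, 4)
  expect_equal(single$gamma, 0.25)

  cfg <- classifier_config(C = c(1, 4, 16), gamma = c(0.5, 0.05), inner_folds = 5)
  got <- grid_search_svm(z, fm$labels, cfg, seed = 7)
  # oracle: independently re-score all pairs over the same partition
  part <- stabselect:::stratified_folds(fm$labels, 5,
                                        seed = stabselect:::child_seed(7, 31))
  grid <- expand.grid(C = cfg$C, gamma = cfg$gamma)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0
    for (hold in part) {
      tr <- setdiff(seq_len(nrow(z)), hold)
      fit <- e1071::svm(z[tr, ], fm$labels[tr], kernel = "radial",
                        cost = grid$C[g], gamma = grid$gamma[g], scale = FALSE)
      correct <- correct + sum(predict(fit, z[hold, , drop = FALSE]) ==
                                 fm$labels[hold])
    }
    acc[g] <- correct / nrow(z)
  }
  best <- order(-acc, grid$C, -grid$gamma)[1]
  expect_equal(got$C, grid$C[best])
  expect_equal(got$gamma, grid$gamma[best])
  expect_equal(got$grid$accuracy, acc)
})

test_that("nested CV reports the fold mean and scores separable data highly", {
  fm <- tiny_fm(n_per_group = 10, p = 12, seed = 5, d = 6)  # margin >> noise
  cv <- nested_cv(fm, make_selector("ttest", k = 4),
                  classifier_config(C = 4, gamma = 2^-4), seed = 2)
  expect_equal(cv$acc, mean(cv$fold_acc))
  expect_length(cv$fold_acc, 10)
  expect_gte(cv$acc, 0.95)
  expect_length(cv$feature_sets, 10)
  expect_true(all(lengths(cv$feature_sets) == 4))
  expect_true(cv$ki >= -1 && cv$ki <= 1)
})

test_that("no information leaks from validation folds into fitted parameters", {
  fm <- tiny_fm(n_per_group = 8, p = 10, seed = 6, d = 1.5)
  cfg <- classifier_config(C = 4, gamma = 2^-4)
  sel <- make_selector("ttest", k = 3)
  base <- nested_cv(fm, sel, cfg, seed = 11)
  # 8 per class: the outer partition is clipped to 8 stratified folds
  part <- stabselect:::stratified_folds(fm$labels, 8,
                                        seed = stabselect:::child_seed(11, 41))
  # corrupt the rows held out in fold 1: fold 1's fitted normalisation,
  # selection and hyperparameters must not change
  fm2 <- fm
  fm2$values[part[[1]], ] <- fm2$values[part[[1]], ] * 50 + 7
  mod <- nested_cv(fm2, sel, cfg, seed = 11)
  expect_identical(mod$fold_models[[1]]$norm, base$fold_models[[1]]$norm)
  expect_identical(mod$fold_models[[1]]$features, base$fold_models[[1]]$features)
  expect_identical(mod$fold_models[[1]]$svm$coefs, base$fold_models[[1]]$svm$coefs)
})

test_that("independent testing averages per-model confusion metrics", {
  # stub models with fixed predictions exercise the confusion arithmetic:
  # TP=6, FN=1, TN=4, FP=3 on a 7+7 test set
  y <- factor(rep(c("autistic", "non-autistic"), each = 7))
  pred <- factor(c(rep("autistic", 6), "non-autistic",
                   rep("non-autistic", 4), rep("autistic", 3)),
                 levels = levels(y))
  registerS3method("predict", "stub_model", function(object, newdata, ...)
    object$pred, envir = globalenv())
  ids <- sprintf("kinematic.general.direct.m%02d.mean", 1:3)
  vals <- matrix(rnorm(14 * 3), 14, 3, dimnames = list(NULL, ids))
  testset <- feature_matrix(vals, y)
  mod <- list(norm = fit_zscore(vals), features = ids,
              svm = structure(list(pred = pred), class = "stub_model"))
  res <- independent_test(list(mod, mod), testset)
  expect_equal(res$sensitivity, 6 / 7, tolerance = 1e-12)
  expect_equal(res$specificity, 4 / 7, tolerance = 1e-12)
  expect_equal(res$accuracy, 10 / 14)
  # balanced test set: accuracy = (sensitivity + specificity) / 2
  expect_equal(res$accuracy, (res$sensitivity + res$specificity) / 2)
  # identical models average to the single model's metrics
  expect_equal(res$per_model[1, ], res$per_model[2, ], ignore_attr = TRUE)
})

test_that("repeated runs reduce to one run and summarise their own distribution", {
  fm <- tiny_fm(n_per_group = 8, p = 10, seed = 8, d = 2)
  tst <- tiny_fm(n_per_group = 4, p = 10, seed = 9, d = 2)
  cfg <- classifier_config(C = 4, gamma = 2^-4)
  sel <- make_selector("ttest", k = 3)
  one <- repeat_runs(fm, tst, sel, cfg, n_repeats = 1, seed = 5)
  direct <- nested_cv(fm, sel, cfg, seed = stabselect:::child_seed(5, 1))
  expect_equal(one$runs$dev_acc, direct$acc)
  expect_equal(one$runs$test_acc,
               independent_test(direct$fold_models, tst)$accuracy)

  res <- repeat_runs(fm, tst, sel, cfg, n_repeats = 8, seed = 5)
  expect_equal(nrow(res$runs), 8)
  # distribution summaries equal a recount over the stored values
  expect_equal(res$summary$median[res$summary$metric == "dev_acc"],
               median(res$runs$dev_acc))
  expect_equal(res$summary$q1[res$summary$metric == "test_acc"],
               unname(quantile(res$runs$test_acc, 0.25)))
  # identical seed reproduces the whole trace
  res2 <- repeat_runs(fm, tst, sel, cfg, n_repeats = 8, seed = 5)
  expect_identical(res$runs, res2$runs)
})

test_that("permutation p follows the add-one empirical formula", {
  fm <- tiny_fm(n_per_group = 8, p = 12, seed = 10, d = 5)
  tst <- tiny_fm(n_per_group = 4, p = 12, seed = 11, d = 5)
  cfg <- classifier_config(C = 4, gamma = 2^-4)
  sel <- make_selector("ttest", k = 3)
  # strong signal: the observed accuracy beats every permutation
  pt <- permutation_significance(fm, tst, sel, cfg, n_perm = 19, seed = 3)
  expect_equal(pt$p, (sum(pt$permuted >= pt$observed) + 1) / 20)
  expect_gte(pt$observed, 0.9)
  # observed at/below every permuted value gives p = 1
  pt2 <- permutation_significance(fm, tst, sel, cfg, n_perm = 9, seed = 4,
                                  observed = 0)
  expect_equal(pt2$p, 1)
  expect_error(permutation_significance(fm, tst, sel, cfg, n_perm = 0),
               "n_perm")
})
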