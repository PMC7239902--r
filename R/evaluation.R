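#' SVM-RBF classifier configuration
#'
#' The hyperparameter grids and inner cross-validation used by the
#' evaluation engine: `C = 2^j, j = 1..7` and `gamma = 2^i, i = -1..-7`,
#' tuned by inner 10-fold CV accuracy.
#'
#' @param C,gamma candidate grids (positive).
#' @param inner_folds folds of the inner tuning CV.
#' @return object of class `classifier_config`.
#' @export
classifier_config <- function(C = 2^(1:7), gamma = 2^(-(1:7)),
                              inner_folds = 10) {
  stopifnot(length(C) >= 1, length(gamma) >= 1, all(C > 0), all(gamma > 0),
            inner_folds >= 2)
  structure(list(C = C, gamma = gamma, inner_folds = inner_folds),
            class = "classifier_config")
}

#' Grid-search an RBF SVM by inner cross-validation
#'
#' Exhaustively scores every (C, gamma) pair by stratified inner
#' `inner_folds`-fold CV accuracy on the (already normalised) training data
#' and refits the winner on all of it. Ties are broken towards the smallest
#' `C`, then the largest `gamma` (the smoother model).
#'
#' @param x numeric training matrix (z-scored), `y` two-class factor.
#' @param y class labels.
#' @param config a [classifier_config()].
#' @param seed seed for the inner fold partition.
#' @return list: `model` (fitted e1071 SVM on all rows), `C`, `gamma`,
#'   `inner_acc` (CV accuracy of the winning pair), `grid` (data frame of
#'   all pairs and accuracies).
#' @export
grid_search_svm <- function(x, y, config = classifier_config(), seed = 1) {
  y <- factor(y)
  grid <- expand.grid(C = config$C, gamma = config$gamma)
  if (nrow(grid) == 1) {
    fit <- e1071::svm(x, y, kernel = "radial", cost = grid$C, gamma = grid$gamma,
                      scale = FALSE)
    return(list(model = fit, C = grid$C[1], gamma = grid$gamma[1],
                inner_acc = NA_real_,
                grid = cbind(grid, accuracy = NA_real_)))
  }
  k <- min(config$inner_folds, min(table(y)))
  if (k < 2) stop("inner folds infeasible for class sizes")
  part <- stratified_folds(y, k, seed = child_seed(seed, 31))
  correct <- numeric(nrow(grid))
  for (f in seq_along(part)) {
    hold <- part[[f]]
    tr <- setdiff(seq_len(nrow(x)), hold)
    xtr <- x[tr, , drop = FALSE]; xho <- x[hold, , drop = FALSE]
    for (g in seq_len(nrow(grid))) {
      fit <- e1071::svm(xtr, y[tr], kernel = "radial", cost = grid$C[g],
                        gamma = grid$gamma[g], scale = FALSE)
      correct[g] <- correct[g] + sum(predict(fit, xho) == y[hold])
    }
  }
  acc <- correct / nrow(x)
  best <- order(-acc, grid$C, -grid$gamma)[1]
  fit <- e1071::svm(x, y, kernel = "radial", cost = grid$C[best],
                    gamma = grid$gamma[best], scale = FALSE)
  list(model = fit, C = grid$C[best], gamma = grid$gamma[best],
       inner_acc = acc[best], grid = cbind(grid, accuracy = acc))
}

#' Nested cross-validated model development
#'
#' The development engine: 10 stratified outer folds; inside each fold,
#' z-score normalisation is fitted on the training part only, the feature
#' selector is run on the normalised training part, the SVM is grid-searched
#' by inner CV, and the untouched validation part is scored. The development
#' accuracy is the mean of the ten fold accuracies; the ten fitted fold
#' models (normalisation, feature subset, tuned SVM) are retained for
#' independent testing, and Kuncheva's index of the ten fold-wise selections
#' measures selection stability.
#'
#' @param devset a [feature_matrix()] (imputed; not yet normalised).
#' @param selector a selector from [make_selector()].
#' @param config a [classifier_config()].
#' @param seed seed controlling the outer partition, inner partitions and
#'   any selector randomness.
#' @param outer_folds number of outer folds.
#' For the wrapped t-test selector the structure is different, mirroring the
#' method's published form: the wrapped run's own frozen fold partition *is*
#' the outer partition. The selection loop runs once on the development set;
#' at termination every fold selects the identical common set (Kuncheva
#' index 1 by construction), and each fold's model is then grid-searched on
#' that set and scored on its held-out fold.
#'
#' @return list: `acc` (mean development accuracy), `fold_acc`,
#'   `fold_models`, `feature_sets` (per-fold selected ids), `ki`,
#'   `hyper` (per-fold C, gamma); for wrapped runs also `wrapped_state`.
#' @export
nested_cv <- function(devset, selector, config = classifier_config(),
                      seed = 1, outer_folds = 10) {
  stopifnot(inherits(devset, "feature_matrix"))
  y <- devset$labels
  if (nlevels(y) != 2) stop("development set must have exactly two classes")
  outer_folds <- min(outer_folds, min(table(y)))  # every fold must hold data
  if (identical(attr(selector, "method"), "wrapped")) {
    return(nested_cv_wrapped(devset, selector, config, seed, outer_folds))
  }
  part <- stratified_folds(y, outer_folds, seed = child_seed(seed, 41))
  fold_acc <- numeric(outer_folds)
  fold_models <- vector("list", outer_folds)
  feature_sets <- vector("list", outer_folds)
  hyper <- data.frame(C = numeric(outer_folds), gamma = numeric(outer_folds))
  for (f in seq_along(part)) {
    hold <- part[[f]]
    tr <- setdiff(seq_len(nrow(devset$values)), hold)
    prm <- fit_zscore(devset$values[tr, , drop = FALSE])
    ztr <- apply_zscore(prm, devset$values[tr, , drop = FALSE])
    zho <- apply_zscore(prm, devset$values[hold, , drop = FALSE])
    sel <- selector(ztr, y[tr], seed = child_seed(seed, 100 + f))
    gs <- grid_search_svm(ztr[, sel, drop = FALSE], y[tr], config,
                          seed = child_seed(seed, 200 + f))
    pred <- predict(gs$model, zho[, sel, drop = FALSE])
    fold_acc[f] <- mean(pred == y[hold])
    feature_sets[[f]] <- sel
    hyper$C[f] <- gs$C; hyper$gamma[f] <- gs$gamma
    fold_models[[f]] <- list(norm = prm, features = sel, svm = gs$model,
                             C = gs$C, gamma = gs$gamma)
  }
  list(
    acc = mean(fold_acc), fold_acc = fold_acc, fold_models = fold_models,
    feature_sets = feature_sets,
    ki = kuncheva_index(feature_sets, l = ncol(devset$values)),
    hyper = hyper
  )
}

# Wrapped-selector development: one wrapped run over the frozen partition,
# then per-fold tuned models on the common selected set.
nested_cv_wrapped <- function(devset, selector, config, seed, outer_folds) {
  y <- devset$labels
  args <- attr(selector, "args")
  k <- attr(selector, "k")
  wr <- do.call(wrapped_t_select,
                c(list(devset$values, y, k = k, folds = outer_folds,
                       seed = child_seed(seed, 41)), args))
  part <- wr$state$fold_assignment
  sel <- wr$features
  n_folds <- length(part)
  fold_acc <- numeric(n_folds)
  fold_models <- vector("list", n_folds)
  hyper <- data.frame(C = numeric(n_folds), gamma = numeric(n_folds))
  for (f in seq_len(n_folds)) {
    hold <- part[[f]]
    tr <- setdiff(seq_len(nrow(devset$values)), hold)
    prm <- fit_zscore(devset$values[tr, , drop = FALSE])
    ztr <- apply_zscore(prm, devset$values[tr, , drop = FALSE])
    zho <- apply_zscore(prm, devset$values[hold, , drop = FALSE])
    gs <- grid_search_svm(ztr[, sel, drop = FALSE], y[tr], config,
                          seed = child_seed(seed, 200 + f))
    fold_acc[f] <- mean(predict(gs$model, zho[, sel, drop = FALSE]) == y[hold])
    hyper$C[f] <- gs$C; hyper$gamma[f] <- gs$gamma
    fold_models[[f]] <- list(norm = prm, features = sel, svm = gs$model,
                             C = gs$C, gamma = gs$gamma)
  }
  feature_sets <- rep(list(sel), n_folds)
  list(
    acc = mean(fold_acc), fold_acc = fold_acc, fold_models = fold_models,
    feature_sets = feature_sets,
    ki = kuncheva_index(feature_sets, l = ncol(devset$values)),
    hyper = hyper, wrapped_state = wr$state
  )
}

#' Test developed fold models on an independent sample
#'
#' Each of the fold models (its normalisation, its feature subset, its
#' tuned SVM) predicts the full held-out test set; accuracy, sensitivity and
#' specificity (positive class = autistic by convention) are computed per
#' model and averaged.
#'
#' @param fold_models `fold_models` from [nested_cv()].
#' @param testset a [feature_matrix()], preprocessed with
#'   development-derived parameters (e.g. imputed with development group
#'   means); normalisation is applied per fold model here.
#' @param positive label treated as positive for sensitivity/specificity.
#' @return list: `accuracy`, `sensitivity`, `specificity` (means over
#'   models), `per_model` data frame.
#' @export
independent_test <- function(fold_models, testset, positive = GROUPS[1]) {
  stopifnot(inherits(testset, "feature_matrix"))
  y <- testset$labels
  per <- lapply(fold_models, function(mod) {
    z <- apply_zscore(mod$norm, testset$values)
    pred <- predict(mod$svm, z[, mod$features, drop = FALSE])
    tp <- sum(pred == positive & y == positive)
    fn <- sum(pred != positive & y == positive)
    tn <- sum(pred != positive & y != positive)
    fp <- sum(pred == positive & y != positive)
    c(accuracy = (tp + tn) / length(y),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  per <- as.data.frame(do.call(rbind, per))
  list(accuracy = mean(per$accuracy), sensitivity = mean(per$sensitivity),
       specificity = mean(per$specificity), per_model = per)
}

#' Repeated model development and testing
#'
#' Repeats [nested_cv()] plus [independent_test()] `n_repeats` times with
#' fresh outer-fold partitions to obtain performance distributions
#' (medians, quartiles) of development and testing metrics.
#'
#' @inheritParams nested_cv
#' @param testset independent test [feature_matrix()] (already imputed with
#'   development-derived parameters), or `NULL` to skip testing.
#' @param n_repeats number of repetitions.
#' @return object of class `evaluation_result`: data frame `runs` (one row
#'   per repeat: development accuracy, KI, testing metrics), `summary`
#'   (medians and quartiles), and the last repeat's `fold_models`.
#' @export
repeat_runs <- function(devset, testset, selector,
                        config = classifier_config(), n_repeats = 50,
                        seed = 1) {
  runs <- vector("list", n_repeats)
  last <- NULL
  for (r in seq_len(n_repeats)) {
    dev <- nested_cv(devset, selector, config, seed = child_seed(seed, r))
    row <- data.frame(repeat_id = r, dev_acc = dev$acc, ki = dev$ki)
    if (!is.null(testset)) {
      tst <- independent_test(dev$fold_models, testset)
      row$test_acc <- tst$accuracy
      row$test_sens <- tst$sensitivity
      row$test_spec <- tst$specificity
    }
    runs[[r]] <- row
    last <- dev
  }
  runs <- do.call(rbind, runs)
  num <- runs[, setdiff(names(runs), "repeat_id"), drop = FALSE]
  summary <- data.frame(
    metric = names(num),
    median = vapply(num, median, 0),
    q1 = vapply(num, quantile, 0, probs = 0.25),
    q3 = vapply(num, quantile, 0, probs = 0.75),
    mean = vapply(num, mean, 0)
  )
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, fold_models = last$fold_models),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %d repeats\n", nrow(x$runs)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Permutation significance of the classification result
#'
#' Class labels are permuted (within the development set and, when present,
#' within the test set, preserving each set's balance) and the entire
#' development-and-testing pipeline — normalisation, feature selection,
#' hyperparameter tuning, independent testing — is rerun per permutation.
#' The empirical p-value is
#' `(count of permuted results >= observed + 1) / (n_perm + 1)`, so with 100
#' permutations the smallest attainable p is 1/101 (< 0.01).
#'
#' @inheritParams repeat_runs
#' @param observed observed statistic to compare against (testing accuracy
#'   when a test set is supplied, else development accuracy). If `NULL`, it
#'   is computed first with the unpermuted labels.
#' @param n_perm number of label permutations.
#' @return list: `p`, `observed`, `permuted` (the null statistics).
#' @export
permutation_significance <- function(devset, testset = NULL, selector,
                                     config = classifier_config(),
                                     n_perm = 100, seed = 1,
                                     observed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  run_once <- function(dv, tt, sd) {
    cv <- nested_cv(dv, selector, config, seed = sd)
    if (!is.null(tt)) independent_test(cv$fold_models, tt)$accuracy else cv$acc
  }
  if (is.null(observed)) {
    observed <- run_once(devset, testset, child_seed(seed, 900))
  }
  permuted <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(child_seed(seed, 1000 + i))
    dv <- devset
    dv$labels <- sample(dv$labels)
    tt <- testset
    if (!is.null(tt)) tt$labels <- sample(tt$labels)
    permuted[i] <- run_once(dv, tt, child_seed(seed, 2000 + i))
  }
  list(p = (sum(permuted >= observed) + 1) / (n_perm + 1),
       observed = observed, permuted = permuted)
}
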