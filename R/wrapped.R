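# Stratified k-fold partition: returns a list of held-out index vectors.
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- factor(y)
  folds <- vector("list", k)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    grp <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[grp == f])
  }
  lapply(folds, sort)
}

#' Wrapped t-test feature selection
#'
#' A stability-driven hybrid of filter and wrapper selection. Features are
#' ranked by absolute two-sample t statistic plus an accumulated per-feature
#' adjustment (initially zero). In every iteration, for each of `folds`
#' cross-validation folds (the partition is frozen for the whole run): the
#' top `k` features by adjusted score on the fold's training part are
#' selected, an RBF-kernel SVM is trained on them (z-scored within fold) and
#' scored on the held-out fold; if the fold accuracy exceeds 50% (chance for
#' balanced two-class data) the `k` selected features' adjustments are
#' increased by `delta`, if below 50% decreased by `delta`, at exactly 50%
#' left unchanged. After the folds, Kuncheva's index of the fold-wise
#' selections is computed; the algorithm terminates once the index has been
#' exactly 1 (all folds selecting the identical set) for `stable_runs`
#' consecutive iterations, returning that common set.
#'
#' Adjustments are applied fold-sequentially within an iteration. The SVM
#' hyperparameters are fixed (no per-iteration grid search); final reported
#' models are tuned separately by the evaluation engine.
#'
#' @param x numeric matrix (samples x features), feature ids as column
#'   names. Balanced two-class data is assumed (the 50% chance level).
#' @param y two-class factor.
#' @param k features to select per fold.
#' @param delta adjustment magnitude per fold per iteration (default
#'   0.0001; larger values converge in fewer iterations).
#' @param stable_runs consecutive iterations with index 1 required to stop.
#' @param folds number of cross-validation folds.
#' @param cost,gamma fixed SVM-RBF hyperparameters used inside the loop.
#' @param max_iter iteration cap; exceeding it raises a condition of class
#'   `stabselect_nonconvergence` carrying the accumulated state.
#' @param seed seed for the (frozen) fold partition.
#' @param record_trace keep the per-iteration fold selections (needed to
#'   replay the adjustment trajectory; disable to save memory on very long
#'   runs).
#' @return list with `features` (the common selected set, ids), and `state`:
#'   `adjustments` (named per-feature), `iterations`, `converged`,
#'   `ki` (per-iteration index trajectory), `fold_acc` (iterations x folds
#'   accuracy matrix), `mean_acc`, `selections` (if recorded: per iteration,
#'   list of per-fold selected id sets), `fold_assignment`, `delta`,
#'   `consecutive_stable`.
#' @export
wrapped_t_select <- function(x, y, k = 10, delta = 1e-4, stable_runs = 100,
                             folds = 10, cost = 4, gamma = 2^-4,
                             max_iter = 1e5, seed = 1,
                             record_trace = TRUE) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("need exactly two classes")
  ids <- colnames(x)
  p <- length(ids)
  if (k >= p) stop("k must be smaller than the number of features")
  folds <- min(folds, min(table(y)))  # every fold must hold data
  part <- stratified_folds(y, folds, seed = child_seed(seed, 21))

  # Per-fold constants: the base |t| ranking statistics and the z-scored
  # train/held-out data never change because the partition is frozen.
  fold_const <- lapply(part, function(hold) {
    tr <- setdiff(seq_len(nrow(x)), hold)
    prm <- fit_zscore(x[tr, , drop = FALSE])
    list(
      hold = hold, train = tr,
      base = abs(pooled_t(x[tr, , drop = FALSE], y[tr])),
      ztrain = apply_zscore(prm, x[tr, , drop = FALSE]),
      zhold = apply_zscore(prm, x[hold, , drop = FALSE])
    )
  })

  adjustments <- setNames(numeric(p), ids)
  acc_cache <- lapply(seq_len(folds), function(i) new.env(parent = emptyenv()))
  ki_trace <- numeric(0)
  acc_list <- list()
  sel_trace <- if (record_trace) list() else NULL
  consecutive <- 0L
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    sets <- vector("list", folds)
    accs <- numeric(folds)
    for (f in seq_len(folds)) {
      fc <- fold_const[[f]]
      score <- fc$base + adjustments
      sel <- order_features(score, fc$base, ids)[seq_len(k)]
      key <- paste(sel, collapse = ",")
      acc <- acc_cache[[f]][[key]]
      if (is.null(acc)) {
        fit <- e1071::svm(fc$ztrain[, sel, drop = FALSE], y[fc$train],
                          kernel = "radial", cost = cost, gamma = gamma,
                          scale = FALSE)
        pred <- predict(fit, fc$zhold[, sel, drop = FALSE])
        acc <- mean(pred == y[fc$hold])
        assign(key, acc, envir = acc_cache[[f]])
      }
      if (acc > 0.5) {
        adjustments[sel] <- adjustments[sel] + delta
      } else if (acc < 0.5) {
        adjustments[sel] <- adjustments[sel] - delta
      }
      sets[[f]] <- ids[sel]
      accs[f] <- acc
    }
    ki <- kuncheva_index(sets, l = p)
    identical_sets <- all(vapply(sets[-1], setequal, TRUE, sets[[1]]))
    consecutive <- if (identical_sets) consecutive + 1L else 0L
    ki_trace[iter] <- ki
    acc_list[[iter]] <- accs
    if (record_trace) sel_trace[[iter]] <- sets
    if (consecutive >= stable_runs) break
  }

  acc_trace <- do.call(rbind, acc_list)
  state <- list(
    adjustments = adjustments, iterations = iter,
    converged = consecutive >= stable_runs,
    ki = ki_trace, fold_acc = unname(acc_trace),
    mean_acc = rowMeans(acc_trace),
    selections = sel_trace,
    fold_assignment = part, delta = delta,
    consecutive_stable = consecutive
  )
  if (!state$converged) {
    cond <- structure(
      class = c("stabselect_nonconvergence", "error", "condition"),
      list(message = sprintf(
        "wrapped t-test did not reach %d stable iterations within %d iterations",
        stable_runs, max_iter), call = sys.call(), state = state)
    )
    stop(cond)
  }
  list(features = sort(sets[[1]]), state = state)
}

#' Replay the wrapped t-test adjustment trajectory from its logged state
#'
#' Re-executes the accumulation rule (+/- delta per fold per iteration,
#' driven by the logged fold accuracies and selections) independently of the
#' selection loop and returns the reconstructed final adjustment vector.
#' Useful for auditing a run: the result must equal `state$adjustments`.
#'
#' @param state the `state` element returned by [wrapped_t_select()] (with
#'   recorded selections).
#' @param feature_ids full feature-id universe of the run.
#' @return named numeric vector of reconstructed adjustments.
#' @export
replay_adjustments <- function(state, feature_ids) {
  if (is.null(state$selections)) stop("state has no recorded selections")
  adj <- setNames(numeric(length(feature_ids)), feature_ids)
  for (i in seq_len(state$iterations)) {
    for (f in seq_along(state$selections[[i]])) {
      acc <- state$fold_acc[i, f]
      sel <- state$selections[[i]][[f]]
      if (acc > 0.5) adj[sel] <- adj[sel] + state$delta
      else if (acc < 0.5) adj[sel] <- adj[sel] - state$delta
    }
  }
  adj
}
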