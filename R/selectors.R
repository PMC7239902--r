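#' Ranked features
#'
#' Light container for one selector's output on one training set: feature
#' ids ordered best-first with their ranking scores.
#' @param ids character ids, best first.
#' @param scores numeric scores aligned with `ids`.
#' @param method method tag.
#' @return object of class `ranked_features`.
#' @export
ranked_features <- function(ids, scores, method) {
  structure(list(ids = ids, scores = scores, method = method),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("<ranked_features> method=%s, %d features; top: %s\n",
              x$method, length(x$ids),
              paste(head(x$ids, 3), collapse = ", ")))
  invisible(x)
}

# Deterministic tie-break used by every selector: primary score (desc),
# then |t| on the same training data (desc), then feature id (lexicographic).
order_features <- function(primary, tstats, ids) {
  order(-primary, -abs(tstats), ids, method = "radix")
}

# Vectorized pooled-variance two-sample t statistics, one per column.
# Constant-within-both-groups features with equal means get t = 0; zero
# pooled variance with unequal means gives +/-Inf.
pooled_t <- function(x, y) {
  y <- factor(y)
  if (nlevels(y) != 2) stop("need exactly two classes")
  g1 <- y == levels(y)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per class")
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  se <- sp * sqrt(1 / n1 + 1 / n2)
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  t
}

#' Rank features by two-sample t statistic
#'
#' Features are ordered by descending absolute pooled-variance two-sample
#' t: how different the feature means are between the two classes.
#'
#' @param x numeric matrix (samples x features) with feature ids as column
#'   names.
#' @param y two-class factor.
#' @return a [ranked_features()].
#' @export
t_rank <- function(x, y) {
  t <- pooled_t(x, y)
  ord <- order_features(abs(t), t, colnames(x))
  ranked_features(colnames(x)[ord], abs(t)[ord], "ttest")
}

#' Rank features by recursive SVM weight elimination (SVM-RFE)
#'
#' Repeatedly fits a linear-kernel SVM and eliminates the fraction of
#' remaining features with the smallest squared weights; the ranking is the
#' reverse elimination order (features within an eliminated batch are
#' ordered by their weights at elimination time).
#'
#' @inheritParams t_rank
#' @param frac fraction of remaining features dropped per iteration (at
#'   least one); `frac = 0` drops exactly one per iteration.
#' @param cost linear SVM cost parameter.
#' @return a [ranked_features()]; scores are reverse elimination ranks.
#' @export
svm_rfe_rank <- function(x, y, frac = 0.1, cost = 1) {
  y <- factor(y)
  tstats <- pooled_t(x, y)
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(x[, remaining, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    ndrop <- max(1L, floor(frac * length(remaining)))
    # worst (smallest weight) first so that reversing gives best-first
    ord <- order_features(w^2, tstats[remaining], remaining)
    drop_ids <- remaining[rev(ord)][seq_len(ndrop)]
    eliminated <- c(eliminated, drop_ids)
    remaining <- setdiff(remaining, drop_ids)
  }
  ids <- c(remaining, rev(eliminated))
  ranked_features(ids, rev(seq_along(ids)), "svmrfe")
}

#' Rank features by ReliefF weights
#'
#' Instance-based weighting: for every sample, features are rewarded for
#' separating it from its nearest misses (other class) and penalised for
#' differing from its nearest hits (same class). Distances are Manhattan on
#' range-normalized features; all samples are used.
#'
#' @inheritParams t_rank
#' @param n_neighbors nearest hits/misses per sample (clipped to class
#'   size - 1).
#' @return a [ranked_features()]; scores are the ReliefF weights.
#' @export
relieff_rank <- function(x, y, n_neighbors = 10) {
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  y <- factor(y)
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  xn <- sweep(x, 2, rng, "/")
  d <- as.matrix(stats::dist(xn, method = "manhattan"))
  w <- numeric(ncol(x))
  priors <- table(y) / n
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    k_h <- min(n_neighbors, length(same))
    hits <- same[order(d[i, same])][seq_len(k_h)]
    diff_h <- abs(sweep(xn[hits, , drop = FALSE], 2, xn[i, ], "-"))
    w <- w - colSums(diff_h) / (k_h * n)
    for (cl in levels(y)[levels(y) != y[i]]) {
      opp <- which(y == cl)
      k_m <- min(n_neighbors, length(opp))
      miss <- opp[order(d[i, opp])][seq_len(k_m)]
      diff_m <- abs(sweep(xn[miss, , drop = FALSE], 2, xn[i, ], "-"))
      w <- w + (priors[[cl]] / (1 - priors[[as.character(y[i])]])) *
        colSums(diff_m) / (k_m * n)
    }
  }
  names(w) <- colnames(x)
  ord <- order_features(w, pooled_t(x, y), colnames(x))
  ranked_features(colnames(x)[ord], w[ord], "relieff")
}

# Mutual information (nats) between two discrete vectors.
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / outer(px, py)[keep]))
}

# 3-bin discretization at mean +/- SD.
discretize3 <- function(x) {
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(2L, length(x)))
  findInterval(x, c(m - s, m + s)) + 1L
}

#' Rank features by greedy mRMR (minimum redundancy, maximum relevance)
#'
#' Features are discretized to 3 bins at mean +/- SD; greedy MID selection
#' maximises mutual information with the class label minus the mean mutual
#' information with already-selected features (MIQ, the quotient scheme, is
#' available via `scheme`). The selection order is the ranking.
#'
#' @inheritParams t_rank
#' @param n_rank how many features to rank (the greedy order is the
#'   ranking); default all.
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @return a [ranked_features()]; scores are the greedy criterion values.
#' @export
mrmr_rank <- function(x, y, n_rank = ncol(x), scheme = c("MID", "MIQ")) {
  scheme <- match.arg(scheme)
  y <- factor(y)
  disc <- apply(x, 2, discretize3)
  p <- ncol(x)
  rel <- vapply(seq_len(p), function(j) discrete_mi(disc[, j], y), 0)
  tstats <- pooled_t(x, y)
  ids <- colnames(x)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)   # running sum of MI(candidate, selected)
  for (step in seq_len(min(n_rank, p))) {
    cand <- setdiff(seq_len(p), selected)
    crit <- if (length(selected) == 0) {
      rel[cand]
    } else if (scheme == "MID") {
      rel[cand] - red_sum[cand] / length(selected)
    } else {
      rel[cand] / pmax(red_sum[cand] / length(selected), .Machine$double.eps)
    }
    pick <- cand[order_features(crit, tstats[cand], ids[cand])[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[match(pick, cand)])
    if (length(selected) < n_rank) {
      upd <- setdiff(seq_len(p), selected)
      red_sum[upd] <- red_sum[upd] + vapply(upd, function(j)
        discrete_mi(disc[, j], disc[, pick]), 0)
    }
  }
  ranked_features(ids[selected], scores, "mrmr")
}

#' Ensemble feature selection by rank aggregation
#'
#' Combines the SVM-RFE, t-test, mRMR and ReliefF rankings by Borda voting
#' (sum of rank positions, lower is better) and returns the `k` best
#' features. Ties are broken by |t|, then feature id.
#'
#' @inheritParams t_rank
#' @param k number of features to select.
#' @return character vector of `k` feature ids, with the rank-sum table in
#'   attribute `"rank_sums"`.
#' @export
ensemble_select <- function(x, y, k = 10) {
  if (k > ncol(x)) stop("k exceeds feature count")
  ids <- colnames(x)
  rankers <- list(t_rank(x, y), svm_rfe_rank(x, y), mrmr_rank(x, y),
                  relieff_rank(x, y))
  pos <- vapply(rankers, function(r) match(ids, r$ids), integer(length(ids)))
  sums <- rowSums(pos)
  names(sums) <- ids
  ord <- order_features(-sums, pooled_t(x, y), ids)
  out <- ids[ord][seq_len(k)]
  attr(out, "rank_sums") <- sums
  out
}

#' t-test feature selection with bagging (stability selection)
#'
#' The t-test ranking is run `n_bags` times on stratified random
#' subsamples of half the data; the `k` features most frequently appearing
#' in the per-bag top-`k` sets are selected. Frequency ties are broken by
#' mean |t| across bags, then feature id.
#'
#' @inheritParams ensemble_select
#' @param n_bags number of subsamples.
#' @param seed integer seed for the subsample draws.
#' @return character vector of `k` feature ids; attributes `"frequency"`
#'   (named count vector), `"bags"` (list of row-index vectors) and
#'   `"top_sets"` (per-bag top-k ids) support independent recounting.
#' @export
bagged_t_select <- function(x, y, k = 10, n_bags = 100, seed = 1) {
  y <- factor(y)
  set.seed(child_seed(seed, 11))
  split_idx <- split(seq_len(nrow(x)), y)
  half <- lapply(split_idx, function(i) floor(length(i) / 2))
  if (any(unlist(half) < 2)) stop("class too small to subsample (need >= 4)")
  freq <- setNames(numeric(ncol(x)), colnames(x))
  tsum <- setNames(numeric(ncol(x)), colnames(x))
  bags <- vector("list", n_bags)
  tops <- vector("list", n_bags)
  for (bnum in seq_len(n_bags)) {
    rows <- unlist(lapply(names(split_idx), function(g)
      sample(split_idx[[g]], half[[g]])), use.names = FALSE)
    bags[[bnum]] <- sort(rows)
    t <- pooled_t(x[rows, , drop = FALSE], y[rows])
    ord <- order_features(abs(t), t, colnames(x))
    top <- colnames(x)[ord][seq_len(k)]
    tops[[bnum]] <- top
    freq[top] <- freq[top] + 1
    tsum <- tsum + abs(t)
  }
  ord <- order(-freq, -tsum / n_bags, names(freq), method = "radix")
  out <- names(freq)[ord][seq_len(k)]
  attr(out, "frequency") <- freq
  attr(out, "bags") <- bags
  attr(out, "top_sets") <- tops
  out
}

#' Selector factory
#'
#' Wraps each selection method behind a uniform interface
#' `function(x, y, seed)` returning exactly `k` feature ids, as used by
#' [nested_cv()].
#'
#' @param method one of `"ttest"`, `"svmrfe"`, `"relieff"`, `"mrmr"`,
#'   `"ensemble"`, `"bagged"`, `"wrapped"`.
#' @param k number of features each call selects.
#' @param ... method-specific arguments (e.g. `n_bags`, `delta`,
#'   `stable_runs`).
#' @return a function of class `stabselect_selector`.
#' @export
make_selector <- function(method = c("ttest", "svmrfe", "relieff", "mrmr",
                                     "ensemble", "bagged", "wrapped"),
                          k = 10, ...) {
  method <- match.arg(method)
  dots <- list(...)
  fn <- switch(method,
    ttest = function(x, y, seed = 1) head(t_rank(x, y)$ids, k),
    svmrfe = function(x, y, seed = 1)
      head(do.call(svm_rfe_rank, c(list(x, y), dots))$ids, k),
    relieff = function(x, y, seed = 1)
      head(do.call(relieff_rank, c(list(x, y), dots))$ids, k),
    mrmr = function(x, y, seed = 1)
      do.call(mrmr_rank, c(list(x, y, n_rank = k), dots))$ids,
    ensemble = function(x, y, seed = 1)
      as.character(do.call(ensemble_select, c(list(x, y, k = k), dots))),
    bagged = function(x, y, seed = 1)
      as.character(do.call(bagged_t_select,
                           c(list(x, y, k = k, seed = seed), dots))),
    wrapped = function(x, y, seed = 1)
      do.call(wrapped_t_select,
              c(list(x, y, k = k, seed = seed), dots))$features
  )
  structure(fn, class = c("stabselect_selector", "function"),
            method = method, k = k, args = dots)
}
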