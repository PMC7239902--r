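simple_xy <- function(seed = 1, n_per = 8, p = 6) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
}

test_that("t ranking reproduces hand-computed pooled statistics", {
  # class a {0, 1}, class b {2, 3}: pooled SD 0.7071, |t| = 2.828
  x <- cbind(f1 = c(0, 1, 2, 3), f2 = c(5, 5, 5, 5))
  y <- factor(c("a", "a", "b", "b"))
  t <- stabselect:::pooled_t(x, y)
  expect_equal(unname(abs(t["f1"])), 2 / (sqrt(0.5) * sqrt(1)), tolerance = 1e-12)
  expect_equal(unname(abs(t["f1"])), 2.828, tolerance = 1e-3)
  # a feature identical across classes ranks last with |t| = 0
  r <- t_rank(x, y)
  expect_equal(r$ids, c("f1", "f2"))
  expect_equal(unname(r$scores["f2"] * 0), 0)
  expect_equal(unname(r$scores[2]), 0)
  expect_error(t_rank(x, factor(rep("a", 4))), "two classes")
})

test_that("a strong planted feature is found by t ranking, verified directly", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    x <- matrix(rnorm(30 * 120), 30, 120,
                dimnames = list(NULL, sprintf("f%03d", 1:120)))
    y <- factor(rep(c("a", "b"), each = 15))
    x[y == "a", "f007"] <- x[y == "a", "f007"] + 0.93
    r <- t_rank(x, y)
    # oracle: recompute every t directly with t.test
    t_direct <- vapply(colnames(x), function(f)
      abs(t.test(x[y == "a", f], x[y == "b", f], var.equal = TRUE)$statistic), 0)
    expect_equal(unname(r$scores[match(colnames(x), r$ids)]),
                 unname(t_direct), tolerance = 1e-10)
    if ("f007" %in% r$ids[1:10]) hits <- hits + 1
  }
  expect_gte(hits, 16)   # top-10 in at least 80% of replicates
})

test_that("SVM-RFE elimination matches a step-size-1 refit oracle", {
  set.seed(21)
  n <- 20; p <- 12
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "a", 1:2] <- x[y == "a", 1:2] + 2
  got <- svm_rfe_rank(x, y, frac = 0)   # one feature per iteration

  # oracle: independent loop removing the smallest-|w| feature one at a time
  remaining <- colnames(x)
  order_oracle <- character(0)
  while (length(remaining) > 1) {
    fit <- e1071::svm(x[, remaining, drop = FALSE], y, kernel = "linear",
                      cost = 1, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    worst <- remaining[which.min(w^2)]
    order_oracle <- c(worst, order_oracle)
    remaining <- setdiff(remaining, worst)
  }
  expect_equal(got$ids, c(remaining, order_oracle))
})

test_that("a perfectly separating feature survives SVM-RFE to the final set", {
  set.seed(3)
  x <- matrix(rnorm(24 * 15, sd = 0.3), 24, 15,
              dimnames = list(NULL, sprintf("f%02d", 1:15)))
  y <- factor(rep(c("a", "b"), each = 12))
  x[, "f09"] <- ifelse(y == "a", 3, -3) + rnorm(24, sd = 0.05)
  r <- svm_rfe_rank(x, y)
  expect_equal(r$ids[1], "f09")
  # requesting every feature retains them all
  small <- simple_xy(seed = 5, p = 10)
  expect_setequal(head(svm_rfe_rank(small$x, small$y)$ids, 10),
                  colnames(small$x))
})

test_that("ReliefF reproduces a hand-traced instance and detects interactions", {
  # 6 samples, 2 features; k = 1 neighbour: hand-executed hit/miss updates
  x <- cbind(f1 = c(0, 0.1, 0.2, 1.0, 1.1, 1.2),
             f2 = c(0, 1.0, 0.5, 0.4, 0.9, 0.1))
  y <- factor(c("a", "a", "a", "b", "b", "b"))
  got <- relieff_rank(x, y, n_neighbors = 1)
  # manual trace with range-normalized features and Manhattan distances
  rng <- apply(x, 2, function(v) diff(range(v)))
  xn <- sweep(x, 2, rng, "/")
  w_manual <- c(0, 0)
  for (i in 1:6) {
    d <- colSums(abs(t(xn) - xn[i, ]))
    same <- which(y == y[i] & seq_len(6) != i)
    opp <- which(y != y[i])
    hit <- same[which.min(d[same])]
    miss <- opp[which.min(d[opp])]
    w_manual <- w_manual - abs(xn[i, ] - xn[hit, ]) / 6 +
      abs(xn[i, ] - xn[miss, ]) / 6
  }
  expect_equal(unname(got$scores[match(colnames(x), got$ids)]),
               unname(w_manual), tolerance = 1e-12)

  # XOR layout: two interacting features outrank a weak marginal feature
  set.seed(11)
  n <- 120
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  y2 <- factor(ifelse(xor(a, b), "a", "b"))
  x2 <- cbind(i1 = a + rnorm(n, 0, 0.05), i2 = b + rnorm(n, 0, 0.05),
              weak = ifelse(y2 == "a", 0.2, 0) + rnorm(n, 0, 1))
  r2 <- relieff_rank(x2, y2)
  expect_setequal(r2$ids[1:2], c("i1", "i2"))

  # pure-noise feature has weight near zero at large n
  set.seed(12)
  x3 <- cbind(sig = ifelse(rep(c(TRUE, FALSE), each = 100), 1, 0) +
                rnorm(200, 0, 0.1),
              noise = rnorm(200))
  y3 <- factor(rep(c("a", "b"), each = 100))
  r3 <- relieff_rank(x3, y3)
  expect_lt(abs(r3$scores[r3$ids == "noise"]), 0.05)
  expect_error(relieff_rank(x3, y3, n_neighbors = 0), "n_neighbors")
})

test_that("greedy mRMR selection matches an independent reimplementation", {
  set.seed(31)
  n <- 30; p <- 8
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "a", 1] <- x[y == "a", 1] + 2
  x[y == "a", 5] <- x[y == "a", 5] + 1.2
  got <- mrmr_rank(x, y)

  # oracle: brute-force greedy MID with its own discretizer and MI
  disc <- apply(x, 2, function(v) {
    cut(v, c(-Inf, mean(v) - sd(v), mean(v) + sd(v), Inf), labels = FALSE)
  })
  mi <- function(u, v) {
    tab <- table(u, v); pj <- tab / sum(tab)
    pu <- rowSums(pj); pv <- colSums(pj)
    s <- 0
    for (i in seq_along(pu)) for (j in seq_along(pv)) {
      if (pj[i, j] > 0) s <- s + pj[i, j] * log(pj[i, j] / (pu[i] * pv[j]))
    }
    s
  }
  rel <- vapply(seq_len(p), function(j) mi(disc[, j], y), 0)
  sel <- which.max(rel)
  while (length(sel) < p) {
    cand <- setdiff(seq_len(p), sel)
    crit <- vapply(cand, function(j) {
      rel[j] - mean(vapply(sel, function(s2) mi(disc[, j], disc[, s2]), 0))
    }, 0)
    sel <- c(sel, cand[which.max(crit)])
  }
  expect_equal(got$ids, colnames(x)[sel])
  # first pick is the relevance argmax by definition
  expect_equal(got$ids[1], colnames(x)[which.max(rel)])
})

test_that("mRMR defers a duplicated copy of the top feature", {
  set.seed(32)
  n <- 60
  strong <- c(rnorm(n / 2, 2), rnorm(n / 2, 0))
  weak <- c(rnorm(n / 2, 0.8), rnorm(n / 2, 0))
  x <- cbind(strong = strong, strong_dup = strong, weak = weak)
  y <- factor(rep(c("a", "b"), each = n / 2))
  r <- mrmr_rank(x, y)
  expect_equal(r$ids[1], "strong")   # id tie-break between identical copies
  expect_equal(r$ids[2], "weak")     # novel but weaker beats the redundant copy
})

test_that("ensemble voting equals a brute-force Borda oracle", {
  dat <- simple_xy(seed = 41, n_per = 10, p = 12)
  x <- dat$x; y <- dat$y
  x[y == "a", 1:3] <- x[y == "a", 1:3] + 1.5
  got <- ensemble_select(x, y, k = 5)
  rankers <- list(t_rank(x, y), svm_rfe_rank(x, y), mrmr_rank(x, y),
                  relieff_rank(x, y))
  sums <- rowSums(vapply(rankers, function(r) match(colnames(x), r$ids),
                         integer(ncol(x))))
  names(sums) <- colnames(x)
  oracle <- names(sort(sums))[1:5]
  expect_setequal(as.character(got), oracle)
  expect_equal(unname(attr(got, "rank_sums")), unname(sums))

  # all four rankings identical -> ensemble top-k equals each ranker's top-k
  x1 <- cbind(s1 = c(rep(3, 6), rep(0, 6)) + rnorm(12, 0, 0.01),
              s2 = c(rep(2, 6), rep(0, 6)) + rnorm(12, 0, 0.01),
              n1 = rnorm(12, 0, 0.01))
  y1 <- factor(rep(c("a", "b"), each = 6))
  expect_equal(as.character(ensemble_select(x1, y1, k = 2)),
               head(t_rank(x1, y1)$ids, 2))
})

test_that("score ties break towards the larger |t|, then the smaller id", {
  prim <- c(a = 1, b = 1, c = 0)
  tst <- c(a = 0.5, b = 2, c = 9)
  ord <- stabselect:::order_features(prim, tst, names(prim))
  expect_equal(names(prim)[ord], c("b", "a", "c"))
  # and id-lexicographic as the final tie-break
  prim2 <- c(z = 1, y = 1)
  tst2 <- c(z = 1, y = 1)
  ord2 <- stabselect:::order_features(prim2, tst2, names(prim2))
  expect_equal(names(prim2)[ord2], c("y", "z"))
})

test_that("bagged t selection recounts exactly and collapses to t at one bag", {
  dat <- simple_xy(seed = 51, n_per = 10, p = 15)
  x <- dat$x; y <- dat$y
  x[y == "a", 1] <- x[y == "a", 1] + 4   # dominant feature
  got <- bagged_t_select(x, y, k = 3, n_bags = 50, seed = 9)
  expect_equal(unname(attr(got, "frequency")[colnames(x)[1]]), 50)

  # independent recount over the recorded subsamples
  bags <- attr(got, "bags")
  freq <- setNames(numeric(ncol(x)), colnames(x))
  for (rows in bags) {
    tt <- vapply(colnames(x), function(f)
      abs(t.test(x[rows, f][y[rows] == "a"], x[rows, f][y[rows] == "b"],
                 var.equal = TRUE)$statistic), 0)
    top <- names(sort(tt, decreasing = TRUE))[1:3]
    freq[top] <- freq[top] + 1
  }
  expect_equal(attr(got, "frequency"), freq)

  # n_bags = 1 reduces to the t ranking on that subsample
  one <- bagged_t_select(x, y, k = 3, n_bags = 1, seed = 10)
  rows <- attr(one, "bags")[[1]]
  expect_setequal(as.character(one),
                  head(t_rank(x[rows, , drop = FALSE], y[rows])$ids, 3))
  few <- c(1, 2, 11, 12)   # two per class: half-size bags need >= 4 per class
  expect_error(bagged_t_select(x[few, ], y[few], k = 2), "too small")
})

test_that("selectors are deterministic and invariant to row/column order", {
  dat <- simple_xy(seed = 61, n_per = 9, p = 10)
  x <- dat$x; y <- dat$y
  x[y == "a", 2] <- x[y == "a", 2] + 1
  for (method in c("ttest", "svmrfe", "relieff", "mrmr", "ensemble", "bagged")) {
    sel <- make_selector(method, k = 4)
    a <- sel(x, y, seed = 3)
    b <- sel(x, y, seed = 3)
    expect_identical(a, b)
    expect_length(a, 4)
    # column permutation leaves the selected identifiers unchanged
    permc <- sample(ncol(x))
    c2 <- sel(x[, permc, drop = FALSE], y, seed = 3)
    expect_setequal(a, c2)
  }
  # row permutation (with labels) leaves deterministic rankers unchanged
  permr <- sample(nrow(x))
  expect_equal(t_rank(x[permr, ], y[permr])$ids, t_rank(x, y)$ids)
  expect_equal(relieff_rank(x[permr, ], y[permr])$ids, relieff_rank(x, y)$ids)
})
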