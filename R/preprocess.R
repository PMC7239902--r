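# Non-recursive outlier criterion of Van Selst & Jolicoeur (1994): the
# SD-multiple cutoff depends on sample size to keep the expected trimming
# rate flat in small samples. Values between tabulated n are linearly
# interpolated; n >= 100 uses 2.50; below n = 4 nothing is removed.
VSJ_TABLE <- data.frame(
  n = c(4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 20, 25, 30, 35, 50, 100),
  c = c(1.458, 1.68, 1.841, 1.961, 2.05, 2.12, 2.173, 2.22, 2.246, 2.274,
        2.31, 2.326, 2.391, 2.41, 2.4305, 2.45, 2.48, 2.5)
)

#' Sample-size-dependent outlier criterion
#'
#' Returns the SD-multiple cutoff C(n) of the non-recursive trimming
#' procedure: observations farther than C(n) x SD from the sample mean are
#' treated as outliers.
#'
#' @param n sample size(s).
#' @return numeric vector of criteria; `NA` for n < 4.
#' @export
outlier_criterion <- function(n) {
  out <- rep(NA_real_, length(n))
  ok <- !is.na(n) & n >= 4
  out[ok] <- approx(VSJ_TABLE$n, VSJ_TABLE$c, xout = pmin(n[ok], 100),
                    rule = 2)$y
  out
}

#' Remove trial-level outliers (non-recursive procedure)
#'
#' Single-pass trimming: values farther than C(n) x SD from the mean are
#' removed, where C(n) is the sample-size-dependent criterion of
#' [outlier_criterion()]. With fewer than 4 observations the input is
#' returned unchanged.
#'
#' @param x numeric vector of one participant's trial values for one measure
#'   (NAs are ignored and dropped from the return value).
#' @return the retained values.
#' @export
remove_trial_outliers <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) return(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x)
  keep <- abs(x - mean(x)) <= outlier_criterion(n) * s
  x[keep]
}

# Logical variant used when positions, not values, must be retained.
flag_outliers <- function(x) {
  out <- rep(FALSE, length(x))
  obs <- which(!is.na(x))
  if (length(obs) < 4) return(out)
  v <- x[obs]
  s <- sd(v)
  if (!is.finite(s) || s == 0) return(out)
  out[obs] <- abs(v - mean(v)) > outlier_criterion(length(v)) * s
  out
}

#' Screen gaze trials for excessive missing data
#'
#' Drops trials whose `missing_fraction` (blinks, pupil/corneal reflection
#' loss as a share of trial duration) exceeds 1/3. The boundary is strict:
#' exactly 1/3 is retained.
#'
#' @param gaze gaze-event data frame (one row per event) with columns
#'   `participant`, `block`, `condition`, `trial`, `missing_fraction`.
#' @return the retained rows.
#' @export
screen_missing_gaze <- function(gaze) {
  if (is.null(gaze$missing_fraction) || anyNA(gaze$missing_fraction)) {
    stop("missing_fraction must be populated for every gaze trial")
  }
  gaze[gaze$missing_fraction <= 1 / 3, , drop = FALSE]
}

#' Group-level outlier replacement and group-mean imputation
#'
#' Per feature and per class: values flagged by the sample-size-dependent
#' C(n) x SD criterion across participants are replaced with the group mean
#' of the non-outlying observations; remaining missing cells are filled with
#' the same group means. No missing values remain afterwards.
#'
#' When `group_means` (a features x groups matrix from a previous,
#' development-set call) is supplied, those reference means are used instead
#' of re-estimating them — this is how an independent test set is imputed
#' without using its own labels' statistics. `strict = TRUE` ignores class
#' labels entirely and uses pooled means (sensitivity analysis mode).
#'
#' @param fm a [feature_matrix()].
#' @param group_means optional reference means (features x groups; pooled
#'   means in a single column if `strict`).
#' @param strict logical; pooled, label-free imputation.
#' @return a [feature_matrix()] with attribute `"group_means"` carrying the
#'   means used (for later test-set imputation).
#' @export
impute_group_outliers_and_missing <- function(fm, group_means = NULL,
                                              strict = FALSE) {
  vals <- fm$values
  groups <- if (strict) factor(rep("pooled", nrow(vals))) else fm$labels
  glev <- levels(groups)
  means_used <- matrix(NA_real_, ncol(vals), length(glev),
                       dimnames = list(colnames(vals), glev))
  for (g in glev) {
    rows <- which(groups == g)
    for (j in seq_len(ncol(vals))) {
      v <- vals[rows, j]
      out <- flag_outliers(v)
      clean <- v[!out & !is.na(v)]
      if (length(clean) == 0) {
        if (is.null(group_means)) {
          stop("feature '", colnames(vals)[j], "' entirely missing in group '",
               g, "'")
        }
        clean_mean <- NA_real_
      } else {
        clean_mean <- mean(clean)
      }
      fill <- if (!is.null(group_means)) group_means[colnames(vals)[j], g]
              else clean_mean
      if (is.na(fill)) {
        stop("no reference mean available for feature '", colnames(vals)[j],
             "' in group '", g, "'")
      }
      v[out | is.na(v)] <- fill
      vals[rows, j] <- v
      means_used[j, g] <- fill
    }
  }
  out_fm <- feature_matrix(vals, fm$labels, fm$feature_meta, fm$sample_ids)
  attr(out_fm, "group_means") <- means_used
  out_fm
}

#' Training-set z-score normalisation
#'
#' `fit_zscore()` estimates per-feature means and unbiased SDs on training
#' rows only; `apply_zscore()` transforms any matrix with those parameters.
#' Constant training features get divisor 1 (recorded in the parameters), so
#' they map to all-zero columns rather than NaN.
#'
#' @param train a [feature_matrix()] or numeric matrix of training rows.
#' @return `fit_zscore()`: an object of class `norm_params` with elements
#'   `mean`, `sd` (fallback 1 where the training SD was 0) and
#'   `constant` (logical).
#' @export
fit_zscore <- function(train) {
  x <- if (inherits(train, "feature_matrix")) train$values else as.matrix(train)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  constant <- !is.finite(s) | s == 0
  s[constant] <- 1
  structure(list(mean = mu, sd = s, constant = constant,
                 features = colnames(x)),
            class = "norm_params")
}

#' @rdname fit_zscore
#' @param params a `norm_params` object from [fit_zscore()].
#' @param x a [feature_matrix()] or numeric matrix with the same features.
#' @return `apply_zscore()`: the transformed object, same type as `x`.
#' @export
apply_zscore <- function(params, x) {
  is_fm <- inherits(x, "feature_matrix")
  vals <- if (is_fm) x$values else as.matrix(x)
  if (!identical(colnames(vals), params$features)) {
    stop("feature mismatch between normalisation parameters and matrix")
  }
  vals <- sweep(sweep(vals, 2, params$mean, "-"), 2, params$sd, "/")
  if (is_fm) feature_matrix(vals, x$labels, x$feature_meta, x$sample_ids)
  else vals
}
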