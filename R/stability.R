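#' Kuncheva's stability index for collections of feature subsets
#'
#' Measures how consistently a selector picks the same features across
#' repeated runs (e.g. cross-validation folds). For `m` subsets
#' \eqn{S_1,\dots,S_m}, each of cardinality `k` drawn from `l` features, the
#' index is the mean over all unordered pairs \eqn{i<j} of the
#' chance-corrected overlap
#' \deqn{\frac{|S_i \cap S_j|\,l - k^2}{k\,(l-k)}.}
#' It equals 1 iff all subsets are identical, and is bounded below by -1
#' (attained by disjoint subsets when `k = l/2`). For independently drawn
#' random subsets its expectation is 0.
#'
#' @param subsets list of at least two feature subsets (character ids or
#'   integer indices), all of the same cardinality `k` with `0 < k < l`.
#' @param l total number of features in the universe the subsets are drawn
#'   from.
#' @return a single number in \[-1, 1\].
#' @examples
#' kuncheva_index(list(1:10, 1:10), l = 168)    # identical -> 1
#' kuncheva_index(list(1:10, 11:20), l = 20)    # disjoint halves -> -1
#' @export
kuncheva_index <- function(subsets, l) {
  if (!is.list(subsets) || length(subsets) < 2) {
    stop("need at least m = 2 subsets")
  }
  ks <- lengths(subsets)
  k <- ks[1]
  if (any(ks != k)) stop("all subsets must have equal cardinality")
  if (any(vapply(subsets, anyDuplicated, 0L) > 0)) {
    stop("subsets must not contain duplicate features")
  }
  if (k <= 0 || k >= l) stop("require 0 < k < l (k = ", k, ", l = ", l, ")")
  m <- length(subsets)
  total <- 0
  for (i in seq_len(m - 1)) {
    si <- subsets[[i]]
    for (j in (i + 1):m) {
      ov <- length(intersect(si, subsets[[j]]))
      total <- total + (ov * l - k^2) / (k * (l - k))
    }
  }
  total / (m * (m - 1) / 2)
}
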