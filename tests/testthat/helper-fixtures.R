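# Shared fixtures built in code.

# A small labelled feature matrix with the canonical id scheme.
tiny_fm <- function(n_per_group = 6, p = 8, seed = 1, d = 0) {
  set.seed(seed)
  ids <- feature_id("kinematic", "general", "direct",
                    paste0("m", sprintf("%02d", seq_len(p))), "mean")
  vals <- matrix(rnorm(2 * n_per_group * p), 2 * n_per_group, p,
                 dimnames = list(NULL, ids))
  labels <- rep(c("autistic", "non-autistic"), each = n_per_group)
  vals[labels == "autistic", 1] <- vals[labels == "autistic", 1] + d
  feature_matrix(vals, labels)
}

# Sampled minimum-jerk point-to-point movement: extent D metres in T
# seconds at fs Hz, with a parabolic vertical arc of height h.
min_jerk_trial <- function(D = 0.15, T = 0.5, fs = 120, h = 0) {
  t <- seq(0, T, by = 1 / fs)
  tau <- t / T
  data.frame(
    t = t,
    x = D * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
    y = 0,
    z = h * 4 * tau * (1 - tau)
  )
}

# Per-trial measure table in the layout aggregate_features() expects.
measure_table <- function(participant, group, condition, values_by_measure,
                          block = "general") {
  n <- length(values_by_measure[[1]])
  base <- data.frame(participant = participant, group = group, block = block,
                     condition = condition, trial = seq_len(n))
  for (ms in stabselect:::KINEMATIC_MEASURES) {
    base[[ms]] <- if (!is.null(values_by_measure[[ms]])) values_by_measure[[ms]]
                  else rep(1, n)
  }
  base
}

# Cohen's d with the pooled (average-variance) denominator.
cohens_d <- function(v, g) {
  a <- v[g == "autistic"]; n <- v[g != "autistic"]
  (mean(a) - mean(n)) / sqrt((var(a) + var(n)) / 2)
}

# The wrapped-selector recovery fixture: the default planted feature set
# scaled to a clearly identifiable signal strength.
recovery_spec <- function() {
  pl <- default_planted_features()
  pl$d <- sign(pl$d) * 1.4
  cohort_spec(planted_features = pl)
}
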