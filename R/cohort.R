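#' Specification of a synthetic two-group cohort
#'
#' Defines the statistical structure of a simulated case-control movement
#' imitation study: development and test sample sizes, trials per condition,
#' planted group effects on named features (standardized mean differences,
#' signed autistic minus non-autistic), target mean inter-feature
#' correlations per modality, and a multiplicative inflation of the autistic
#' group's trial-to-trial variability.
#'
#' The same planted effects are used for development and test draws: one
#' population, two samples.
#'
#' @param n_per_group_dev,n_per_group_test participants per group in the
#'   development and hold-out test samples.
#' @param trials_per_condition movement/gaze trials per participant per
#'   condition per block.
#' @param planted_features data frame with columns `feature_id`, `d`
#'   (Cohen's d, signed autistic minus non-autistic); see
#'   [default_planted_features()]. May have zero rows (null cohort).
#' @param mean_corr_kinematic,mean_corr_eye target mean pairwise
#'   correlations within each modality, in \[0, 1): induced by a single
#'   shared latent factor per modality with loading `sqrt(r)`.
#' @param variability_inflation multiplicative factor on the autistic
#'   group's trial-level noise SDs.
#' @param missing_gaze_fraction share of gaze trials flagged with substantial
#'   data loss (their `missing_fraction` is drawn uniformly on \[0, 0.6\];
#'   other trials get 0).
#' @param blocks which experimental blocks to simulate.
#' @param seed default seed used when generation functions are not given one.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group_dev = 15, n_per_group_test = 7,
                        trials_per_condition = 10,
                        planted_features = default_planted_features(),
                        mean_corr_kinematic = 0.20, mean_corr_eye = 0.48,
                        variability_inflation = 1.3,
                        missing_gaze_fraction = 0.15,
                        blocks = BLOCKS, seed = 1L) {
  stopifnot(
    n_per_group_dev >= 1, n_per_group_test >= 0, trials_per_condition >= 1,
    mean_corr_kinematic >= 0, mean_corr_kinematic < 1,
    mean_corr_eye >= 0, mean_corr_eye < 1,
    variability_inflation > 0,
    missing_gaze_fraction >= 0, missing_gaze_fraction <= 1,
    all(blocks %in% BLOCKS)
  )
  if (is.null(planted_features)) {
    planted_features <- data.frame(feature_id = character(), d = numeric())
  }
  planted_features <- as.data.frame(planted_features)
  if (nrow(planted_features)) {
    if (!all(c("feature_id", "d") %in% names(planted_features))) {
      stop("planted_features needs columns feature_id, d")
    }
    if (!all(is.finite(planted_features$d))) stop("effect sizes must be finite")
    universe <- feature_universe(BLOCKS)
    bad <- setdiff(planted_features$feature_id, universe)
    if (length(bad)) {
      stop("effect planted on unknown feature id: ",
           paste(bad, collapse = ", "))
    }
    if (anyDuplicated(planted_features$feature_id)) {
      stop("duplicate planted feature ids")
    }
  }
  structure(
    list(n_per_group_dev = as.integer(n_per_group_dev),
         n_per_group_test = as.integer(n_per_group_test),
         trials_per_condition = as.integer(trials_per_condition),
         planted_features = planted_features,
         mean_corr_kinematic = mean_corr_kinematic,
         mean_corr_eye = mean_corr_eye,
         variability_inflation = variability_inflation,
         missing_gaze_fraction = missing_gaze_fraction,
         blocks = blocks, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' All feature identifiers of the canonical layout
#'
#' 120 kinematic + 48 eye features per block.
#' @param blocks blocks to include.
#' @return character vector of feature ids.
#' @export
feature_universe <- function(blocks = BLOCKS) {
  unlist(lapply(blocks, function(b) {
    c(
      as.vector(vapply(CONDITIONS, function(cond) {
        as.vector(vapply(KINEMATIC_MEASURES, function(ms)
          feature_id("kinematic", b, cond, ms, STATISTICS),
          character(2)))
      }, character(length(KINEMATIC_MEASURES) * 2))),
      as.vector(vapply(CONDITIONS, function(cond) {
        as.vector(vapply(EYE_MEASURES, function(ms)
          feature_id("eye", b, cond, ms, STATISTICS),
          character(2)))
      }, character(length(EYE_MEASURES) * 2)))
    )
  }), use.names = FALSE)
}

#' Default planted group effects
#'
#' Ten features carrying standardized group differences with magnitudes in
#' 0.75-0.93, concentrated in the elevated condition of the general block:
#' autistic participants show lower vertical amplitude, earlier peak
#' acceleration, later peak deceleration, longer durations, and reduced
#' visual attention to the moving finger. Signs are autistic minus
#' non-autistic.
#'
#' @return data frame with columns `feature_id`, `d`.
#' @export
default_planted_features <- function() {
  data.frame(
    feature_id = c(
      feature_id("kinematic", "general", "elevated", "vertical_amplitude", "mean"),
      feature_id("kinematic", "general", "elevated", "pct_to_peak_acceleration", "mean"),
      feature_id("kinematic", "general", "elevated", "pct_to_peak_deceleration", "mean"),
      feature_id("kinematic", "general", "elevated", "duration", "mean"),
      feature_id("kinematic", "general", "direct", "vertical_amplitude", "mean"),
      feature_id("kinematic", "general", "direct", "duration", "mean"),
      feature_id("kinematic", "general", "direct_fast", "duration", "mean"),
      feature_id("eye", "general", "elevated", "pct_dwell_on_finger", "mean"),
      feature_id("eye", "general", "elevated", "saccade_amplitude", "mean"),
      feature_id("eye", "general", "direct", "fixation_duration", "mean")
    ),
    d = c(-0.93, -0.75, 0.90, 0.85, -0.78, 0.76, 0.80, -0.88, -0.82, -0.79)
  )
}

# ---------------------------------------------------------------------------
# Generator parameter tables (plausibility-scaled; see methods vignette).

KIN_BASE <- list(
  direct = list(dur = 0.60, height = 0.025),
  elevated = list(dur = 0.70, height = 0.085),
  direct_fast = list(dur = 0.38, height = 0.020)
)
# between-participant / within-participant (trial) SDs
KIN_SD <- list(
  dur = c(b = 0.050, w = 0.030),
  height = c(b = 0.012, w = 0.006),
  shape = c(b = 0.12, w = 0.18)     # beta-profile exponents p, q
)
POS_NOISE_SD <- 0.0005              # m, per coordinate per sample
MOVE_EXTENT <- 0.15                 # m between pointing locations

EYE_BASE <- list(
  saccade_count = 4, saccade_amplitude = 6, saccade_duration = 45,
  saccade_peak_velocity = 220, first_saccade_latency = 250,
  fixation_duration = 350, dwell_share = 0.55, gaze_finger_distance = 3
)
EYE_SD <- list(  # c(between, within-trial, event-level)
  saccade_count = c(0.8, 1.1, 0),
  saccade_amplitude = c(0.9, 1.3, 0.8),
  saccade_duration = c(4, 6, 5),
  saccade_peak_velocity = c(18, 25, 15),
  first_saccade_latency = c(35, 55, 0),
  fixation_duration = c(55, 75, 60),
  dwell_share = c(0.07, 0.06, 0),
  gaze_finger_distance = c(0.5, 0.7, 0.4)
)

# Trial-plantable measures: those with a direct generator parameter.
PLANTABLE_KIN <- c("vertical_amplitude", "duration",
                   "pct_to_peak_acceleration", "pct_to_peak_deceleration")
PLANTABLE_EYE <- setdiff(EYE_MEASURES, "saccade_count")

# ---------------------------------------------------------------------------
# Timing geometry of the beta-profile velocity family v(tau) ~
# tau^p (1-tau)^q.  p = q = 2 is exactly the minimum-jerk profile.  The
# normalized times of peak acceleration/deceleration depend only on (p, q).

beta_profile_timings <- function(p, q) {
  tau <- seq(0.0005, 0.9995, length.out = 2001)
  v <- dbeta(tau, p + 1, q + 1)
  a <- central_diff(v, tau)
  c(pct_a = 100 * tau[which.max(a)], pct_d = 100 * tau[which.min(a)])
}

# 2x2 Jacobian of (pct_a, pct_d) w.r.t. (p, q) at the minimum-jerk baseline.
timing_jacobian <- function(h = 0.05) {
  f0 <- beta_profile_timings(2, 2)
  jp <- (beta_profile_timings(2 + h, 2) - beta_profile_timings(2 - h, 2)) / (2 * h)
  jq <- (beta_profile_timings(2, 2 + h) - beta_profile_timings(2, 2 - h)) / (2 * h)
  list(J = cbind(p = jp, q = jq), baseline = f0)
}

# ---------------------------------------------------------------------------

# Pooled SD of a participant-level mean feature when the autistic group's
# trial noise is inflated by v and features average T trials.
pooled_feature_sd <- function(sd_b, sd_w, T, v) {
  sqrt(sd_b^2 + (v^2 + 1) / 2 * sd_w^2 / T)
}

# Resolve planted effects into per-(block, condition) generator-parameter
# shifts for the autistic group.
plan_trial_effects <- function(spec) {
  pl <- spec$planted_features
  if (nrow(pl)) {
    meta <- parse_feature_ids(pl$feature_id)
    if (any(meta$statistic != "mean")) {
      stop("trial-level planting supports mean-statistic features only; ",
           "offending id(s): ",
           paste(pl$feature_id[meta$statistic != "mean"], collapse = ", "))
    }
    bad <- (meta$modality == "kinematic" & !(meta$measure %in% PLANTABLE_KIN)) |
      (meta$modality == "eye" & !(meta$measure %in% PLANTABLE_EYE))
    if (any(bad)) {
      stop("effect planted on feature without a generator parameter: ",
           paste(pl$feature_id[bad], collapse = ", "))
    }
    meta$d <- pl$d
  } else {
    meta <- cbind(parse_feature_ids(character(0)), d = numeric(0))
  }
  v <- spec$variability_inflation
  T <- spec$trials_per_condition
  tj <- timing_jacobian()
  # between/within SDs of the two timing percentages induced by (p, q)
  pct_b <- sqrt(rowSums((tj$J * rep(KIN_SD$shape["b"], each = 2))^2))
  pct_w <- sqrt(rowSums((tj$J * rep(KIN_SD$shape["w"], each = 2))^2))

  shifts <- list()
  for (b in spec$blocks) {
    for (cond in CONDITIONS) {
      sel <- meta$block == b & meta$condition == cond
      sub <- meta[sel, , drop = FALSE]
      s <- list(dur = 0, height = 0, p = 0, q = 0,
                eye = setNames(numeric(length(EYE_MEASURES)), EYE_MEASURES))
      dd <- function(measure) {
        i <- which(sub$modality == "kinematic" & sub$measure == measure)
        if (length(i)) sub$d[i] else 0
      }
      s$dur <- dd("duration") *
        pooled_feature_sd(KIN_SD$dur["b"], KIN_SD$dur["w"], T, v)
      s$height <- dd("vertical_amplitude") *
        pooled_feature_sd(KIN_SD$height["b"], KIN_SD$height["w"], T, v)
      delta_pct <- c(
        dd("pct_to_peak_acceleration") * pooled_feature_sd(pct_b[1], pct_w[1], T, v),
        dd("pct_to_peak_deceleration") * pooled_feature_sd(pct_b[2], pct_w[2], T, v)
      )
      pq <- solve(tj$J, delta_pct)
      s$p <- pq[1]; s$q <- pq[2]
      for (ms in PLANTABLE_EYE) {
        i <- which(sub$modality == "eye" & sub$measure == ms)
        if (length(i)) {
          key <- if (ms == "pct_dwell_on_finger") "dwell_share" else ms
          sdv <- EYE_SD[[key]]
          s$eye[ms] <- sub$d[i] * pooled_feature_sd(sdv[1], sdv[2], T, v)
        }
      }
      shifts[[paste(b, cond, sep = ".")]] <- s
    }
  }
  shifts
}

participant_roster <- function(spec) {
  mk <- function(set, grp, tag, n) {
    if (n == 0) return(NULL)
    data.frame(
      participant = sprintf("%s_%s%02d", set, tag, seq_len(n)),
      group = grp, set = set, stringsAsFactors = FALSE
    )
  }
  rbind(
    mk("dev", GROUPS[1], "a", spec$n_per_group_dev),
    mk("dev", GROUPS[2], "n", spec$n_per_group_dev),
    mk("test", GROUPS[1], "a", spec$n_per_group_test),
    mk("test", GROUPS[2], "n", spec$n_per_group_test)
  )
}

#' Generate trial-level movement and gaze recordings
#'
#' Simulates the full cohort: per participant, `trials_per_condition` trials
#' for each of 3 conditions x the requested blocks. Movement trajectories
#' follow a smooth bell-velocity (beta-family, minimum-jerk at baseline)
#' longitudinal profile over 0.15 m plus a parabolic vertical component,
#' sampled at 120 Hz with measurement noise. Gaze trials carry pre-parsed
#' saccade and fixation events. Group effects are injected at the generator
#' parameters so that downstream extracted features carry (approximately)
#' the planted effect sizes; autistic trial-level noise SDs are multiplied
#' by `variability_inflation`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (defaults to `spec$seed`).
#' @return list with `movement` (long data frame, one row per 120 Hz sample:
#'   participant, group, set, block, condition, trial, t, x, y, z), `gaze`
#'   (one row per saccade/fixation event, with per-trial
#'   `missing_fraction`), and `participants` (the roster).
#' @export
generate_trials <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(seed, 1))
  roster <- participant_roster(spec)
  shifts <- plan_trial_effects(spec)
  v_of <- function(grp) if (grp == GROUPS[1]) spec$variability_inflation else 1

  move_parts <- list()
  gaze_parts <- list()
  idx <- 0L
  for (r in seq_len(nrow(roster))) {
    pid <- roster$participant[r]
    grp <- roster$group[r]
    vg <- v_of(grp)
    is_a <- grp == GROUPS[1]
    for (b in spec$blocks) {
      for (cond in CONDITIONS) {
        s <- shifts[[paste(b, cond, sep = ".")]]
        base <- KIN_BASE[[cond]]
        # participant-level kinematic parameters
        th_dur <- base$dur + is_a * s$dur + rnorm(1, 0, KIN_SD$dur["b"])
        th_h <- base$height + is_a * s$height + rnorm(1, 0, KIN_SD$height["b"])
        th_p <- 2 + is_a * s$p + rnorm(1, 0, KIN_SD$shape["b"])
        th_q <- 2 + is_a * s$q + rnorm(1, 0, KIN_SD$shape["b"])
        # participant-level eye parameters
        th_eye <- vapply(EYE_MEASURES, function(ms) {
          key <- if (ms == "pct_dwell_on_finger") "dwell_share" else ms
          EYE_BASE[[key]] + is_a * s$eye[ms] + rnorm(1, 0, EYE_SD[[key]][1])
        }, 0)
        for (tr in seq_len(spec$trials_per_condition)) {
          idx <- idx + 1L
          dur <- max(0.22, th_dur + rnorm(1, 0, vg * KIN_SD$dur["w"]))
          h <- max(0.003, th_h + rnorm(1, 0, vg * KIN_SD$height["w"]))
          p <- max(0.6, th_p + rnorm(1, 0, vg * KIN_SD$shape["w"]))
          q <- max(0.6, th_q + rnorm(1, 0, vg * KIN_SD$shape["w"]))
          n <- round(dur * 120) + 1
          t <- (seq_len(n) - 1) / 120
          tau <- t / t[n]
          move_parts[[idx]] <- list(
            meta = c(pid, grp, roster$set[r], b, cond), trial = tr, n = n,
            t = t,
            x = MOVE_EXTENT * pbeta(tau, p + 1, q + 1) +
              rnorm(n, 0, vg * POS_NOISE_SD),
            y = rnorm(n, 0, vg * POS_NOISE_SD),
            z = h * 4 * tau * (1 - tau) + rnorm(n, 0, vg * POS_NOISE_SD)
          )
          gaze_parts[[idx]] <- simulate_gaze_trial(
            pid, grp, roster$set[r], b, cond, tr, th_eye, vg,
            trial_dur_ms = (base$dur + 1.0) * 1000,
            missing_prob = spec$missing_gaze_fraction
          )
        }
      }
    }
  }
  list(
    movement = bind_trial_parts(move_parts, c("t", "x", "y", "z")),
    gaze = bind_trial_parts(gaze_parts, c("missing_fraction", "event_type",
                                          "onset", "duration", "amplitude",
                                          "peak_velocity", "on_finger",
                                          "finger_distance")),
    participants = roster
  )
}

# Assemble per-trial vector bundles into one long data frame without the
# per-trial data.frame/rbind overhead.
bind_trial_parts <- function(parts, value_cols) {
  ns <- vapply(parts, function(p) as.integer(p$n), 0L)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  out <- data.frame(
    participant = rep(meta[, 1], ns), group = rep(meta[, 2], ns),
    set = rep(meta[, 3], ns), block = rep(meta[, 4], ns),
    condition = rep(meta[, 5], ns),
    trial = rep(vapply(parts, function(p) as.integer(p$trial), 0L), ns),
    stringsAsFactors = FALSE
  )
  for (cl in value_cols) {
    out[[cl]] <- unlist(lapply(parts, `[[`, cl), use.names = FALSE)
  }
  out
}

simulate_gaze_trial <- function(pid, grp, set, block, cond, tr, th, vg,
                                trial_dur_ms, missing_prob) {
  w <- function(ms) EYE_SD[[ms]][2] * vg
  ev <- function(ms) EYE_SD[[ms]][3] * vg
  n_sac <- max(1, round(th["saccade_count"] + rnorm(1, 0, w("saccade_count"))))
  amp_t <- max(0.5, th["saccade_amplitude"] + rnorm(1, 0, w("saccade_amplitude")))
  sdur_t <- max(12, th["saccade_duration"] + rnorm(1, 0, w("saccade_duration")))
  pv_t <- max(40, th["saccade_peak_velocity"] +
                rnorm(1, 0, w("saccade_peak_velocity")))
  lat_t <- max(60, th["first_saccade_latency"] +
                 rnorm(1, 0, w("first_saccade_latency")))
  fdur_t <- max(80, th["fixation_duration"] + rnorm(1, 0, w("fixation_duration")))
  share_t <- min(0.98, max(0.02, th["pct_dwell_on_finger"] +
                             rnorm(1, 0, w("dwell_share"))))
  dist_t <- max(0.2, th["gaze_finger_distance"] +
                  rnorm(1, 0, w("gaze_finger_distance")))

  onsets <- sort(c(lat_t, runif(n_sac - 1, min(lat_t + 50, trial_dur_ms - 110),
                                trial_dur_ms - 100)))
  sac <- list(
    onset = onsets,
    duration = pmax(8, sdur_t + rnorm(n_sac, 0, ev("saccade_duration"))),
    amplitude = pmax(0.2, amp_t + rnorm(n_sac, 0, ev("saccade_amplitude"))),
    peak_velocity = pmax(30, pv_t + rnorm(n_sac, 0, ev("saccade_peak_velocity")))
  )
  n_fix <- n_sac + 1
  fdur <- pmax(40, fdur_t + rnorm(n_fix, 0, ev("fixation_duration")))
  # mark fixations on the finger, in random order, until the realized
  # duration share is as close as possible to the target share
  ord <- sample.int(n_fix)
  cum <- cumsum(fdur[ord]) / sum(fdur)
  k <- which.min(abs(c(0, cum) - share_t)) - 1L
  on <- logical(n_fix)
  if (k > 0) on[ord[seq_len(k)]] <- TRUE
  fix <- list(
    onset = sort(runif(n_fix, 0, trial_dur_ms - 50)),
    duration = fdur,
    on_finger = as.integer(on),
    finger_distance = pmax(0.05, dist_t +
                             rnorm(n_fix, 0, ev("gaze_finger_distance")))
  )
  missing <- if (runif(1) < missing_prob) runif(1, 0, 0.6) else 0
  n_ev <- n_sac + n_fix
  list(
    meta = c(pid, grp, set, block, cond), trial = tr, n = n_ev,
    missing_fraction = rep(missing, n_ev),
    event_type = rep(c("saccade", "fixation"), c(n_sac, n_fix)),
    onset = c(sac$onset, fix$onset),
    duration = c(sac$duration, fix$duration),
    amplitude = c(sac$amplitude, rep(NA_real_, n_fix)),
    peak_velocity = c(sac$peak_velocity, rep(NA_real_, n_fix)),
    on_finger = c(rep(NA_integer_, n_sac), fix$on_finger),
    finger_distance = c(rep(NA_real_, n_sac), fix$finger_distance)
  )
}

#' Directly sample a feature matrix with the assumed population structure
#'
#' Bypasses trial simulation: draws a samples x features matrix (120
#' kinematic + 48 eye columns per requested block) from a correlated
#' Gaussian model. Each modality shares one latent factor with loading
#' `sqrt(r)`, so the mean pairwise within-modality correlation equals the
#' target `r`; columns are standardized (unit variance). Planted effects
#' shift the autistic group's mean of the named columns by `d` SD units
#' (exact by construction). Variability inflation is emulated by a positive
#' mean shift of `0.5 * (variability_inflation - 1)` SD on every
#' SD-statistic column for the autistic group.
#'
#' @param spec a [cohort_spec()].
#' @param n_per_group participants per group (default: the development
#'   sample size).
#' @param blocks blocks to generate columns for (default `"general"`:
#'   168 features).
#' @param seed integer seed.
#' @param prefix sample-id prefix.
#' @return a [feature_matrix()] with balanced labels.
#' @export
generate_feature_matrix <- function(spec, n_per_group = spec$n_per_group_dev,
                                    blocks = "general", seed = spec$seed,
                                    prefix = "s") {
  stopifnot(inherits(spec, "cohort_spec"), n_per_group >= 1)
  set.seed(child_seed(seed, 2))
  draw_feature_matrix(spec, n_per_group, blocks, prefix)
}

draw_feature_matrix <- function(spec, n_per_group, blocks, prefix) {
  ids <- feature_universe(blocks)
  meta <- parse_feature_ids(ids)
  n <- 2L * n_per_group
  labels <- rep(GROUPS, each = n_per_group)
  rmod <- c(kinematic = spec$mean_corr_kinematic, eye = spec$mean_corr_eye)
  vals <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  for (mod in unique(meta$modality)) {
    cols <- which(meta$modality == mod)
    r <- rmod[[mod]]
    f <- rnorm(n)
    eps <- matrix(rnorm(n * length(cols)), n)
    vals[, cols] <- sqrt(r) * f + sqrt(1 - r) * eps
  }
  a_rows <- labels == GROUPS[1]
  pl <- spec$planted_features
  if (nrow(pl)) {
    present <- intersect(pl$feature_id, ids)
    for (fid in present) {
      vals[a_rows, fid] <- vals[a_rows, fid] + pl$d[pl$feature_id == fid]
    }
  }
  sd_cols <- meta$statistic == "SD"
  if (spec$variability_inflation != 1) {
    vals[a_rows, sd_cols] <- vals[a_rows, sd_cols] +
      0.5 * (spec$variability_inflation - 1)
  }
  feature_matrix(vals, labels, meta,
                 sample_ids = sprintf("%s_%s%02d", prefix,
                                      rep(c("a", "n"), each = n_per_group),
                                      rep(seq_len(n_per_group), 2)))
}

#' Draw matched development and test feature matrices
#'
#' Two draws from the same population model (same planted effects and
#' correlation structure), sized `n_per_group_dev` and `n_per_group_test`.
#'
#' @inheritParams generate_feature_matrix
#' @return list with elements `dev` and `test` ([feature_matrix()]s).
#' @export
generate_cohort_matrices <- function(spec, blocks = "general",
                                     seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(seed, 3))
  list(
    dev = draw_feature_matrix(spec, spec$n_per_group_dev, blocks, "dev"),
    test = draw_feature_matrix(spec, spec$n_per_group_test, blocks, "test")
  )
}

#' Read/write trial and gaze tables as TSV
#'
#' Long-format tab-separated files: movement has one row per 120 Hz sample,
#' gaze one row per saccade/fixation event.
#'
#' @param x data frame (`movement` or `gaze` element of
#'   [generate_trials()]).
#' @param path file path.
#' @export
write_trials_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
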