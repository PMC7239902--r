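#' Zero-phase low-pass filtering of a movement trajectory
#'
#' Positions are filtered forward and backward with a Butterworth low-pass
#' filter (zero phase, so the effective gain is the squared single-pass
#' gain). The series is padded by odd reflection at both ends before
#' filtering to suppress edge transients on ramp-like trajectories;
#' timestamps are unchanged.
#'
#' @param trial data frame with columns `t` (seconds, strictly increasing at
#'   a nominal sampling interval) and `x`, `y`, `z` (metres). Extra columns
#'   are preserved.
#' @param cutoff_hz low-pass cutoff in Hz; must be below the Nyquist
#'   frequency implied by the timestamps. 10 Hz is a conventional choice for
#'   reaching movements.
#' @param order filter order (single pass). Default 4.
#' @return the trial with filtered `x`, `y`, `z`.
#' @export
filter_trajectory <- function(trial, cutoff_hz = 10, order = 4) {
  n <- nrow(trial)
  if (n < 8) stop("trial too short to filter (", n, " samples, need >= 8)")
  dt <- diff(trial$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  fs <- 1 / stats::median(dt)
  if (cutoff_hz >= fs / 2 - 1e-9) {
    stop(sprintf("cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
                 cutoff_hz, fs / 2))
  }
  bf <- butter_cached(order, cutoff_hz / (fs / 2))
  for (col in c("x", "y", "z")) {
    trial[[col]] <- filtfilt_padded(bf, trial[[col]])
  }
  trial
}

# Butterworth designs are cached: extraction filters thousands of trials
# with identical settings.
.butter_cache <- new.env(parent = emptyenv())
butter_cached <- function(order, w) {
  key <- sprintf("%d|%.10g", order, w)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, w, type = "low")
    assign(key, bf, envir = .butter_cache)
  }
  bf
}

# One direct-form IIR pass via the C-backed stats::filter (MA part as
# one-sided convolution, AR part recursively).
iir_pass <- function(b, a, x) {
  nb <- length(b)
  u <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  u <- u[-seq_len(nb - 1)]
  if (length(a) > 1) {
    u <- stats::filter(u, -a[-1], method = "recursive")
  }
  as.numeric(u)
}

# filtfilt with odd-reflection end padding (as done by scipy's filtfilt):
# the signal is extended by point-reflected copies so that ramps continue
# smoothly through the boundaries, then filtered forward and backward.
# Each pass filters the deviation from the pass's first sample, which makes
# a constant input an exact fixed point (steady-state initial conditions).
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  npad <- min(n - 1, max(9 * (length(bf$a) - 1), 24))
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - npad)]
  gdc <- sum(bf$b) / sum(bf$a)
  pass <- function(v) iir_pass(bf$b, bf$a, v - v[1]) + v[1] * gdc
  y <- pass(c(pre, x, post))
  y <- rev(pass(rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Per-trial kinematic measures
#'
#' Computes the 20 canonical per-movement measures from a filtered
#' trajectory: speed-based (duration, peak/mean velocity and timing),
#' longitudinal acceleration-based (peak acceleration/deceleration,
#' their timings as % of movement duration, mean absolute acceleration),
#' jerk-based (peak, timing, mean squared, duration/amplitude-normalized),
#' and spatial (vertical and horizontal amplitude, path length,
#' straightness ratio, velocity-peak count, deceleration-phase fraction).
#'
#' Derivatives use central differences on the filtered positions (one-sided
#' at the endpoints). The longitudinal axis is the start-to-end chord;
#' vertical amplitude is the z-range (z is perpendicular to the table
#' plane). Peak deceleration is reported as the magnitude of the most
#' negative longitudinal acceleration. Timing percentages are relative to
#' movement duration.
#'
#' @param trial filtered trial data frame (`t`, `x`, `y`, `z`).
#' @return named numeric vector of length 20 (names are the canonical
#'   measure ids).
#' @export
compute_measures <- function(trial) {
  n <- nrow(trial)
  if (n < 5) stop("degenerate trial: ", n, " samples (need >= 5)")
  t <- trial$t
  duration <- t[n] - t[1]
  if (duration <= 0) stop("degenerate trial: zero duration")
  p <- cbind(trial$x, trial$y, trial$z)

  chord_vec <- p[n, ] - p[1, ]
  chord <- sqrt(sum(chord_vec^2))
  u <- if (chord > 0) chord_vec / chord else c(1, 0, 0)

  v_vec <- central_diff(p, t)
  speed <- sqrt(rowSums(v_vec^2))
  a_vec <- central_diff(v_vec, t)
  j_vec <- central_diff(a_vec, t)
  jerk <- sqrt(rowSums(j_vec^2))

  s_long <- drop((p - matrix(p[1, ], n, 3, byrow = TRUE)) %*% u)
  v_long <- central_diff(s_long, t)
  a_long <- central_diff(v_long, t)

  pct <- function(i) 100 * (t[i] - t[1]) / duration

  i_pv <- which.max(speed)
  i_pa <- which.max(a_long)
  i_pd <- which.min(a_long)
  i_pj <- which.max(jerk)
  i_ph <- which.max(p[, 3])

  seg <- sqrt(rowSums(diff(p)^2))
  path_length <- sum(seg)

  # trapezoid integral of squared jerk for the dimensionless jerk index
  dtv <- diff(t)
  int_j2 <- sum((jerk[-n]^2 + jerk[-1]^2) / 2 * dtv)
  amp <- if (chord > 0) chord else max(path_length, .Machine$double.eps)

  peaks <- which(diff(sign(diff(speed))) < 0) + 1
  peaks <- peaks[speed[peaks] > 0.05 * speed[i_pv]]
  if (length(peaks) == 0 && speed[i_pv] > 0) peaks <- i_pv

  c(
    duration = duration,
    peak_velocity = speed[i_pv],
    mean_velocity = path_length / duration,
    pct_to_peak_velocity = pct(i_pv),
    peak_acceleration = a_long[i_pa],
    pct_to_peak_acceleration = pct(i_pa),
    peak_deceleration = -a_long[i_pd],
    pct_to_peak_deceleration = pct(i_pd),
    mean_abs_acceleration = mean(abs(a_long)),
    peak_jerk = jerk[i_pj],
    pct_to_peak_jerk = pct(i_pj),
    mean_squared_jerk = mean(jerk^2),
    normalized_jerk = sqrt(0.5 * int_j2 * duration^5 / amp^2),
    vertical_amplitude = max(p[, 3]) - min(p[, 3]),
    pct_to_peak_height = pct(i_ph),
    horizontal_amplitude = max(s_long) - min(s_long),
    path_length = path_length,
    straightness_ratio = if (chord > 0) path_length / chord else 1,
    n_velocity_peaks = length(peaks),
    deceleration_fraction = (t[n] - t[i_pv]) / duration
  )
}

# Central differences with one-sided endpoints; works on vectors and
# column-wise on matrices.
central_diff <- function(x, t) {
  if (is.matrix(x)) {
    n <- nrow(x)
    d <- matrix(0, n, ncol(x))
    d[1, ] <- (x[2, ] - x[1, ]) / (t[2] - t[1])
    d[n, ] <- (x[n, ] - x[n - 1, ]) / (t[n] - t[n - 1])
    i <- 2:(n - 1)
    d[i, ] <- (x[i + 1, ] - x[i - 1, ]) / (t[i + 1] - t[i - 1])
    return(d)
  }
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

#' Aggregate per-trial measures into the kinematic feature table
#'
#' Per participant and condition, the mean and unbiased SD over trials of
#' each of the 20 base measures form the features: 40 per condition, 120 per
#' block. Participant-condition cells with fewer than `min_trials` retained
#' trials yield missing features (imputed downstream).
#'
#' @param measures data frame of per-trial measures: columns `participant`,
#'   `group`, `block`, `condition`, `trial` plus the 20 measure columns.
#' @param block which block to tabulate.
#' @param min_trials minimum retained trials per participant x condition.
#' @return a [feature_matrix()] with 120 kinematic columns.
#' @export
aggregate_features <- function(measures, block, min_trials = 2) {
  aggregate_measure_table(measures, block, KINEMATIC_MEASURES, "kinematic",
                          min_trials)
}

# Shared mean/SD aggregation over trials for both modalities. Column order
# is condition (slowest) x measure x statistic, matching feature_id().
aggregate_measure_table <- function(measures, block, measure_names, modality,
                                    min_trials = 2, participants = NULL) {
  stopifnot(block %in% BLOCKS)
  unknown <- setdiff(unique(measures$condition), CONDITIONS)
  if (length(unknown)) {
    stop("unknown condition tag(s): ", paste(unknown, collapse = ", "))
  }
  m <- measures[measures$block == block, , drop = FALSE]
  if (is.null(participants)) {
    participants <- unique(m[, c("participant", "group")])
  }
  participants <- participants[order(participants$participant), ]

  ids <- as.vector(vapply(CONDITIONS, function(cond) {
    as.vector(vapply(measure_names, function(ms) {
      feature_id(modality, block, cond, ms, STATISTICS)
    }, character(length(STATISTICS))))
  }, character(length(measure_names) * length(STATISTICS))))

  vals <- matrix(NA_real_, nrow(participants), length(ids),
                 dimnames = list(participants$participant, ids))
  for (r in seq_len(nrow(participants))) {
    for (cond in CONDITIONS) {
      rows <- m$participant == participants$participant[r] & m$condition == cond
      sub <- m[rows, measure_names, drop = FALSE]
      for (ms in measure_names) {
        v <- sub[[ms]][!is.na(sub[[ms]])]
        if (length(v) >= min_trials) {
          vals[r, feature_id(modality, block, cond, ms, "mean")] <- mean(v)
          vals[r, feature_id(modality, block, cond, ms, "SD")] <- sd(v)
        }
      }
    }
  }
  feature_matrix(vals, participants$group,
                 sample_ids = as.character(participants$participant))
}

#' Extract kinematic features from raw trials
#'
#' Convenience pipeline: filter each trial, compute the 20 measures, remove
#' per-participant trial outliers measure-wise (non-recursive C(n) x SD
#' criterion), and aggregate to the 120-column block table.
#'
#' @param trials long-format trial samples (columns `participant`, `group`,
#'   `block`, `condition`, `trial`, `t`, `x`, `y`, `z`).
#' @param block block to extract.
#' @param cutoff_hz,order filter settings, see [filter_trajectory()].
#' @param trim logical; apply trial-level outlier removal per measure.
#' @return a [feature_matrix()].
#' @export
extract_kinematic_features <- function(trials, block, cutoff_hz = 10,
                                       order = 4, trim = TRUE) {
  tab <- trial_measure_table(trials, block, cutoff_hz, order)
  if (trim) {
    key <- interaction(tab$participant, tab$condition, drop = TRUE)
    for (ms in KINEMATIC_MEASURES) {
      tab[[ms]] <- unsplit(lapply(split(tab[[ms]], key), function(v) {
        v[flag_outliers(v)] <- NA
        v
      }), key)
    }
  }
  aggregate_features(tab, block)
}

trial_measure_table <- function(trials, block, cutoff_hz, order) {
  tr <- trials[trials$block == block, , drop = FALSE]
  idx <- split(seq_len(nrow(tr)),
               interaction(tr$participant, tr$condition, tr$trial, drop = TRUE))
  msr <- t(vapply(idx, function(i) {
    one <- tr[i, , drop = FALSE]
    one <- one[order(one$t), , drop = FALSE]
    compute_measures(filter_trajectory(one, cutoff_hz, order))
  }, numeric(length(KINEMATIC_MEASURES))))
  first <- vapply(idx, `[[`, 0L, 1L)
  out <- cbind(
    tr[first, c("participant", "group", "block", "condition", "trial")],
    as.data.frame(msr)
  )
  rownames(out) <- NULL
  out
}
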