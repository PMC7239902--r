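#' Per-trial eye movement measures
#'
#' Summarises one trial's pre-parsed gaze events into the 8 canonical
#' measures: saccade count, mean saccade amplitude (deg), duration (ms) and
#' peak velocity (deg/s), first-saccade latency (ms), mean fixation duration
#' (ms), percentage of fixation time dwelling on the finger, and
#' duration-weighted mean gaze-to-finger distance (deg).
#'
#' @param events data frame of one trial's events: `event_type`
#'   ("saccade"/"fixation"), `onset` (ms), `duration` (ms), `amplitude`,
#'   `peak_velocity`, `on_finger`, `finger_distance` (irrelevant fields NA).
#' @return named numeric vector of length 8.
#' @export
compute_eye_measures <- function(events) {
  sac <- events[events$event_type == "saccade", , drop = FALSE]
  fix <- events[events$event_type == "fixation", , drop = FALSE]
  fixdur <- fix$duration
  total_fix <- sum(fixdur)
  c(
    saccade_count = nrow(sac),
    saccade_amplitude = if (nrow(sac)) mean(sac$amplitude) else NA_real_,
    saccade_duration = if (nrow(sac)) mean(sac$duration) else NA_real_,
    saccade_peak_velocity = if (nrow(sac)) mean(sac$peak_velocity) else NA_real_,
    first_saccade_latency = if (nrow(sac)) min(sac$onset) else NA_real_,
    fixation_duration = if (nrow(fix)) mean(fixdur) else NA_real_,
    pct_dwell_on_finger = if (total_fix > 0)
      100 * sum(fixdur[fix$on_finger > 0]) / total_fix else NA_real_,
    gaze_finger_distance = if (total_fix > 0)
      sum(fix$finger_distance * fixdur) / total_fix else NA_real_
  )
}

#' Aggregate gaze trials into the 48-column eye feature table
#'
#' Per participant and condition, mean and SD over trials of each of the 8
#' measures: 3 conditions x 8 measures x 2 statistics = 48 features per
#' block. Trials should be pre-screened for missing data
#' ([screen_missing_gaze()]); a participant left with no trials in a
#' condition yields missing features for that condition (imputed
#' downstream).
#'
#' @param gaze long-format gaze events (columns `participant`, `group`,
#'   `block`, `condition`, `trial`, `missing_fraction` plus the event
#'   fields of [compute_eye_measures()]).
#' @param block block to tabulate.
#' @param min_trials minimum trials per participant x condition.
#' @param participants optional roster (data frame with `participant`,
#'   `group`): participants whose trials were all screened out still get an
#'   all-missing row.
#' @return a [feature_matrix()] with 48 eye columns.
#' @export
aggregate_eye_features <- function(gaze, block, min_trials = 2,
                                   participants = NULL) {
  g <- gaze[gaze$block == block, , drop = FALSE]
  idx <- split(seq_len(nrow(g)),
               interaction(g$participant, g$condition, g$trial, drop = TRUE))
  rows <- lapply(idx, function(i) {
    one <- g[i, , drop = FALSE]
    cbind(one[1, c("participant", "group", "block", "condition", "trial")],
          as.data.frame(as.list(compute_eye_measures(one))))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  aggregate_measure_table(tab, block, EYE_MEASURES, "eye", min_trials,
                          participants = participants)
}
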