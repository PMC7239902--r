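# Canonical factor levels used throughout the package.
GROUPS <- c("autistic", "non-autistic")
BLOCKS <- c("general", "attention")
CONDITIONS <- c("direct", "elevated", "direct_fast")
STATISTICS <- c("mean", "SD")

# The 20 per-trial kinematic base measures (per condition, x mean/SD = 40
# features per condition, 120 per block).
KINEMATIC_MEASURES <- c(
  "duration", "peak_velocity", "mean_velocity", "pct_to_peak_velocity",
  "peak_acceleration", "pct_to_peak_acceleration",
  "peak_deceleration", "pct_to_peak_deceleration",
  "mean_abs_acceleration",
  "peak_jerk", "pct_to_peak_jerk", "mean_squared_jerk", "normalized_jerk",
  "vertical_amplitude", "pct_to_peak_height", "horizontal_amplitude",
  "path_length", "straightness_ratio", "n_velocity_peaks",
  "deceleration_fraction"
)

# The 8 per-trial eye movement base measures (x mean/SD x 3 conditions = 48
# features per block).
EYE_MEASURES <- c(
  "saccade_count", "saccade_amplitude", "saccade_duration",
  "saccade_peak_velocity", "first_saccade_latency", "fixation_duration",
  "pct_dwell_on_finger", "gaze_finger_distance"
)

# Derive a reproducible child seed from a root seed and an offset, kept
# within the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 113 * as.numeric(offset)) %%
    2147483647L)
}
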