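# Shared fixtures, built in code and cached per test run.

one_bout_script <- function(intensity = 0.5, load = 5, rate = 1.2,
                            duration = 60, total = NULL) {
  activity_script(data.frame(start_s = 0, duration_s = duration,
                             intensity = intensity, load_kg = load,
                             motion_rate_hz = rate), total_s = total)
}

three_bout_script <- function(duration = 60, gap = 10,
                              intensities = c(0.2, 0.5, 0.9),
                              loads = c(0, 8, 16),
                              rates = c(1.0, 1.5, 2.0)) {
  starts <- (seq_along(intensities) - 1) * (duration + gap)
  activity_script(data.frame(start_s = starts, duration_s = duration,
                             intensity = intensities, load_kg = loads,
                             motion_rate_hz = rates),
                  total_s = max(starts) + duration + gap)
}

quiet_config <- function(seed = 42L) {
  generator_config(seed = seed, vo2_noise_sd = 0, accel_noise_sd = 0,
                   gyro_noise_sd = 0, emg_noise_floor = 0)
}

# small cached cohort + feature table used by several files
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(3, three_bout_script(duration = 30, gap = 5),
                                seed = 7L)
    cache
  }
})

tiny_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_cohort_features(tiny_cohort())
    cache
  }
})

fast_config <- function(arch = "bilstm", seed = 1L, ...) {
  model_config(arch = arch, recurrent_units = 8L, dense_units = 8L,
               max_epochs = 3L, patience = 3L, batch_size = 32L,
               seed = seed, ...)
}

# the 69 published selected-feature names (channel_statistic scheme)
selected_feature_names <- c(
  "Acc_mean", "EMGsum_lag1", "Gyro_mean", "az_per50", "az_median", "az_avg",
  "az_per25", "az_sum", "az_per75", "az_per10", "az_per90", "az_per95",
  "az_per5", "az_max", "ax_max", "gz_stdev", "ax_per95", "gz_min", "gz_max",
  "ax_stdev", "gz_per95", "ax_per90", "ay_stdev", "gz_per5", "az_min",
  "gz_per90", "gz_var", "gx_stdev", "gz_per10", "gx_max", "ax_per75",
  "gx_min", "gy_stdev", "res_gyro_max", "gy_max", "ay_var", "res_acc_skew",
  "res_gyro_per95", "gy_min", "res_gyro_avg", "res_gyro_sum", "ay_min",
  "ax_sum", "ax_var", "gx_var", "res_gyro_median", "res_gyro_per50",
  "res_gyro_stdev", "res_gyro_per90", "gx_per5", "gy_per95", "gz_per75",
  "az_skew", "EMG7_per25", "ax_skew", "res_acc_max", "res_gyro_per75",
  "gy_per5", "gx_per95", "ax_avg", "res_acc_per95", "ax_median", "ax_per50",
  "EMG8_per25", "EMG8_per75", "gy_per10", "EMGsum_var", "res_gyro_per25",
  "gy_per90")
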