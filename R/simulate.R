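# Synthetic armband recordings: first-order VO2 kinetics, IMU motion,
# 8-channel integer EMG, and whole-cohort generation.

#' Simulate a 1 Hz oxygen-uptake trace
#'
#' Integrates first-order uptake kinetics over the activity script: each
#' one-second step moves VO2 toward the intensity-dependent steady state
#' `vo2_rest + intensity * (vo2_peak - vo2_rest)` with time constant
#' `tau_on` when rising and `tau_off` when falling, using the exact
#' discretization `v <- v + (target - v) * (1 - exp(-1/tau))`. Gaussian
#' measurement noise of sd `vo2_noise_sd` is added to the observed series;
#' the noiseless trace is returned alongside as ground truth.
#'
#' @param script an [activity_script()].
#' @param profile a [subject_profile()].
#' @param config a [generator_config()].
#' @return list with `t` (seconds), `vo2` (observed, mL/kg/min) and
#'   `vo2_truth` (noiseless).
#' @export
simulate_vo2_trace <- function(script, profile, config = generator_config()) {
  stopifnot(inherits(script, "activity_script"),
            inherits(profile, "subject_profile"),
            inherits(config, "generator_config"))
  n <- ceiling(script$total_s * config$vo2_rate)
  if (n < 1L) stop_user("script too short for one VO2 sample")
  t <- (seq_len(n) - 1L) / config$vo2_rate
  att <- script_attributes(script, t)
  target <- profile$vo2_rest + att$intensity * (profile$vo2_peak - profile$vo2_rest)
  a_on <- 1 - exp(-1 / (profile$tau_on * config$vo2_rate))
  a_off <- 1 - exp(-1 / (profile$tau_off * config$vo2_rate))
  v <- numeric(n)
  v[1L] <- profile$vo2_rest
  for (k in seq_len(n - 1L)) {
    a <- if (target[k] >= v[k]) a_on else a_off
    v[k + 1L] <- v[k] + (target[k] - v[k]) * a
  }
  noise <- if (config$vo2_noise_sd > 0)
    with_seed(derive_seed(config$seed, "vo2"), rnorm(n, 0, config$vo2_noise_sd))
  else numeric(n)
  list(t = t, vo2 = v + noise, vo2_truth = v)
}

#' Simulate 50 Hz accelerometer and gyroscope streams
#'
#' One accelerometer axis (az) carries the 1 g gravity baseline; each bout
#' adds a sinusoid at its motion rate with amplitude proportional to
#' intensity, phase-shifted across axes, plus white noise. Gyroscope axes
#' are zero-mean sinusoids + noise with amplitude proportional to
#' intensity.
#'
#' @inheritParams simulate_vo2_trace
#' @return list with `t`, `accel` (n x 3, g) and `gyro` (n x 3, deg/s).
#' @export
simulate_imu <- function(script, config = generator_config()) {
  stopifnot(inherits(script, "activity_script"),
            inherits(config, "generator_config"))
  if (any(script$bouts$motion_rate_hz > config$imu_rate / 2))
    stop_user("motion_rate above Nyquist (", config$imu_rate / 2, " Hz)")
  n <- round(script$total_s * config$imu_rate)
  t <- (seq_len(n) - 1L) / config$imu_rate
  att <- script_attributes(script, t)
  # amplitude scales: 0.5 g and 60 deg/s at full intensity
  a_amp <- 0.5 * att$intensity
  g_amp <- 60 * att$intensity
  phase <- 2 * pi * att$motion_rate * t
  accel <- cbind(
    ax = a_amp * sin(phase),
    ay = 0.6 * a_amp * sin(phase + pi / 3),
    az = 1 + 0.8 * a_amp * sin(phase + 2 * pi / 3)
  )
  gyro <- cbind(
    gx = g_amp * sin(phase + pi / 6),
    gy = 0.7 * g_amp * sin(phase + pi / 2),
    gz = 0.9 * g_amp * sin(phase + 5 * pi / 6)
  )
  if (config$accel_noise_sd > 0)
    accel <- accel + with_seed(derive_seed(config$seed, "accel"),
                               matrix(rnorm(3 * n, 0, config$accel_noise_sd), n, 3))
  if (config$gyro_noise_sd > 0)
    gyro <- gyro + with_seed(derive_seed(config$seed, "gyro"),
                             matrix(rnorm(3 * n, 0, config$gyro_noise_sd), n, 3))
  list(t = t, accel = accel, gyro = gyro)
}

# EMG envelope (ADC counts) for given per-sample intensity/load. The 0.2
# baseline activation applies only while the muscle is engaged (intensity
# or load nonzero); at full rest only the instrument noise floor remains.
emg_envelope <- function(intensity, load, gain, floor_sd, channel_gain) {
  engaged <- intensity > 0 | load > 0
  act <- gain * (0.2 + 0.8 * intensity) * (1 + load / 20) * engaged
  channel_gain * (floor_sd + act)
}

#' Simulate the 200 Hz 8-channel integer EMG stream
#'
#' Amplitude-modulated white noise: the per-sample envelope scales with
#' bout intensity and handled load, channels carry distinct fixed gains,
#' and samples are rounded and clipped to the signed 8-bit range
#' \[-128, 127\].
#'
#' @inheritParams simulate_vo2_trace
#' @return list with `t` and `emg` (n x n_emg_channels integer matrix).
#' @export
simulate_emg <- function(script, config = generator_config()) {
  stopifnot(inherits(script, "activity_script"),
            inherits(config, "generator_config"))
  n <- round(script$total_s * config$emg_rate)
  t <- (seq_len(n) - 1L) / config$emg_rate
  att <- script_attributes(script, t)
  nc <- config$n_emg_channels
  # fixed, distinct per-channel gains in [0.6, 1.4]
  ch_gain <- 0.6 + 0.8 * (seq_len(nc) - 1L) / max(1L, nc - 1L)
  z <- with_seed(derive_seed(config$seed, "emg"), matrix(rnorm(n * nc), n, nc))
  emg <- matrix(0L, n, nc, dimnames = list(NULL, paste0("EMG", seq_len(nc))))
  for (j in seq_len(nc)) {
    env <- emg_envelope(att$intensity, att$load, config$emg_gain,
                        config$emg_noise_floor, ch_gain[j])
    emg[, j] <- as.integer(pmax(-128, pmin(127, round(env * z[, j]))))
  }
  list(t = t, emg = emg)
}

#' Simulate one complete recording
#'
#' Runs the VO2, IMU and EMG simulators on a common script and packs the
#' result as a [sensor_recording()] with per-second activity labels and
#' the noiseless VO2 ground truth attached.
#'
#' @inheritParams simulate_vo2_trace
#' @param subject_id identifier string.
#' @return A `sensor_recording`.
#' @export
simulate_recording <- function(script, profile, config = generator_config(),
                               subject_id = "S1") {
  vo2 <- simulate_vo2_trace(script, profile, config)
  imu <- simulate_imu(script, config)
  emg <- simulate_emg(script, config)
  labels <- {
    att <- script_attributes(script, vo2$t)
    ifelse(att$intensity > 0 | att$load > 0, "work", "rest")
  }
  sensor_recording(
    subject_id = subject_id, mass_kg = profile$mass_kg,
    emg = channel_stream("emg", config$emg_rate, 0, emg$emg),
    accel = channel_stream("accel", config$imu_rate, 0, imu$accel),
    gyro = channel_stream("gyro", config$imu_rate, 0, imu$gyro),
    vo2 = channel_stream("vo2", config$vo2_rate, 0,
                         matrix(vo2$vo2, dimnames = list(NULL, "vo2"))),
    vo2_truth = vo2$vo2_truth, labels = labels
  )
}

#' Generate a synthetic cohort
#'
#' Draws per-subject profiles by jittering a base profile deterministically
#' from the master seed (mass ~ N(76.7, 8.25) kg truncated at 50,
#' vo2_rest +/- 0.5, vo2_peak +/- 4 mL/kg/min, tau +/- 5 s), then simulates
#' each subject on the script template with a subject-specific stream seed.
#'
#' @param n_subjects number of subjects (>= 2; leave-one-subject-out needs
#'   at least two).
#' @param script an [activity_script()] shared by all subjects.
#' @param seed master seed.
#' @param config base [generator_config()]; its seed field is overridden
#'   per subject.
#' @param base_profile base [subject_profile()] to jitter.
#' @return list of `sensor_recording`, one per subject, named by subject id.
#' @export
generate_cohort <- function(n_subjects, script, seed = 1L,
                            config = generator_config(),
                            base_profile = subject_profile()) {
  if (n_subjects < 2) stop_user("n_subjects must be >= 2 (LOSO needs >= 2)")
  stopifnot(inherits(script, "activity_script"))
  n_subjects <- as.integer(n_subjects)
  jit <- with_seed(derive_seed(seed, "cohort"), {
    data.frame(
      mass = pmax(50, rnorm(n_subjects, 76.7, 8.25)),
      rest = rnorm(n_subjects, 0, 0.5),
      peak = rnorm(n_subjects, 0, 4),
      tau_on = rnorm(n_subjects, 0, 5),
      tau_off = rnorm(n_subjects, 0, 5)
    )
  })
  recs <- vector("list", n_subjects)
  ids <- sprintf("S%02d", seq_len(n_subjects))
  for (i in seq_len(n_subjects)) {
    prof <- subject_profile(
      mass_kg = jit$mass[i],
      vo2_rest = max(2.5, base_profile$vo2_rest + jit$rest[i]),
      vo2_peak = max(base_profile$vo2_rest + 10, base_profile$vo2_peak + jit$peak[i]),
      tau_on = max(10, base_profile$tau_on + jit$tau_on[i]),
      tau_off = max(10, base_profile$tau_off + jit$tau_off[i])
    )
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("subject-", i))
    recs[[i]] <- simulate_recording(script, prof, cfg, subject_id = ids[i])
  }
  names(recs) <- ids
  recs
}

#' Write a cohort to disk
#'
#' Writes each recording's CSV streams plus a plain-text key-value manifest
#' (subject ids, masses, file paths, seed) that [load_cohort()] consumes.
#'
#' @param cohort list of `sensor_recording` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest for provenance.
#' @return path to the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kv <- list(n_subjects = length(cohort), seed = seed)
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    paths <- write_recording(rec, dir)
    p <- paste0("subject", i, ".")
    kv[[paste0(p, "id")]] <- rec$subject_id
    kv[[paste0(p, "mass_kg")]] <- format(rec$mass_kg, digits = 10)
    for (m in names(paths)) kv[[paste0(p, m)]] <- basename(paths[[m]])
  }
  manifest <- file.path(dir, "manifest.txt")
  write_keyvalue(kv, manifest)
  invisible(manifest)
}

#' Load a cohort from a manifest
#'
#' @param manifest path to a manifest written by [write_cohort()].
#' @return list of `sensor_recording`.
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop_user("manifest not found: ", manifest)
  kv <- read_keyvalue(manifest)
  n <- as.integer(kv_num(kv, "n_subjects"))
  if (is.na(n) || n < 1L) stop_user("manifest has no subjects")
  dir <- dirname(manifest)
  lapply(seq_len(n), function(i) {
    p <- paste0("subject", i, ".")
    entry <- list(
      id = kv_chr(kv, paste0(p, "id")),
      mass_kg = kv_num(kv, paste0(p, "mass_kg")),
      emg = file.path(dir, kv_chr(kv, paste0(p, "emg"))),
      accel = file.path(dir, kv_chr(kv, paste0(p, "accel"))),
      gyro = file.path(dir, kv_chr(kv, paste0(p, "gyro"))),
      vo2 = file.path(dir, kv_chr(kv, paste0(p, "vo2"))),
      labels = {
        f <- kv_chr(kv, paste0(p, "labels"))
        if (is.null(f)) NULL else file.path(dir, f)
      }
    )
    load_recording(entry)
  }) |> stats::setNames(vapply(seq_len(n), function(i)
    kv_chr(kv, paste0("subject", i, ".id")), character(1)))
}
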