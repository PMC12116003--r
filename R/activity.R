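# Activity scripts, subject profiles and generator configuration for the
# synthetic armband cohort.

#' Build an activity script
#'
#' An activity script is an ordered set of non-overlapping work bouts on a
#' common timeline. Seconds not covered by any bout are rest (intensity 0,
#' no load, no rhythmic motion). Intensity is the fraction of the subject's
#' aerobic reserve the bout demands; `load` is the handled mass and drives
#' the EMG envelope; `motion_rate` is the dominant limb oscillation
#' frequency seen by the IMU.
#'
#' @param bouts data.frame with columns `start_s`, `duration_s`,
#'   `intensity` (in \[0, 1\]), `load_kg` (>= 0), `motion_rate_hz` (>= 0).
#' @param total_s total script duration in seconds; defaults to the end of
#'   the last bout.
#' @return An object of class `activity_script`.
#' @export
activity_script <- function(bouts, total_s = NULL) {
  if (is.null(bouts) || nrow(as.data.frame(bouts)) == 0L)
    stop_user("activity script needs at least one bout")
  bouts <- as.data.frame(bouts)
  need <- c("start_s", "duration_s", "intensity", "load_kg", "motion_rate_hz")
  miss <- setdiff(need, names(bouts))
  if (length(miss)) stop_user("bouts missing columns: ", paste(miss, collapse = ", "))
  if (any(bouts$duration_s <= 0)) stop_user("bout durations must be positive")
  if (any(bouts$start_s < 0)) stop_user("bout starts must be non-negative")
  if (any(bouts$intensity < 0 | bouts$intensity > 1))
    stop_user("intensity must lie in [0, 1]")
  if (any(bouts$load_kg < 0)) stop_user("load_kg must be >= 0")
  if (any(bouts$motion_rate_hz < 0)) stop_user("motion_rate_hz must be >= 0")
  bouts <- bouts[order(bouts$start_s), , drop = FALSE]
  ends <- bouts$start_s + bouts$duration_s
  if (nrow(bouts) > 1L && any(bouts$start_s[-1L] < ends[-nrow(bouts)] - 1e-9))
    stop_user("bouts overlap")
  if (is.null(total_s)) total_s <- max(ends)
  check_scalar(total_s, "total_s", lower = 0, strict_lower = TRUE)
  if (total_s < max(ends) - 1e-9) stop_user("total_s shorter than last bout end")
  structure(list(bouts = bouts, total_s = total_s), class = "activity_script")
}

#' @export
print.activity_script <- function(x, ...) {
  cat("<activity_script>", nrow(x$bouts), "bouts over", x$total_s, "s\n")
  print(x$bouts, row.names = FALSE)
  invisible(x)
}

#' Fourteen-bout scaffold-assembly script template
#'
#' A template emulating a scaffold-building session: fourteen manual tasks
#' (walking, carrying/positioning frames, leveling jacks, crossbars,
#' hammering, wrenching, baseboards, guardrails, ladder climbs) mapped to
#' (intensity, load, motion rate) combinations spanning light walking to
#' heavy carrying, separated by rest gaps.
#'
#' @param bout_s duration of each activity bout, seconds.
#' @param rest_s rest gap between consecutive bouts, seconds. The field
#'   protocol rests until heart-rate recovery; here the gap is an explicit
#'   free parameter.
#' @return An `activity_script` with 14 bouts.
#' @export
scaffold_script <- function(bout_s = 300, rest_s = 60) {
  check_scalar(bout_s, "bout_s", lower = 0, strict_lower = TRUE)
  check_scalar(rest_s, "rest_s", lower = 0)
  # intensity / handled load (kg) / dominant motion rate (Hz) per task
  tasks <- data.frame(
    intensity      = c(0.30, 0.80, 0.40, 0.45, 0.50, 0.55, 0.65, 0.50,
                       0.75, 0.70, 0.35, 0.45, 0.55, 0.90),
    load_kg        = c(0, 17.2, 3.0, 3.0, 4.5, 4.5, 1.0, 1.0,
                       15.0, 15.0, 2.3, 2.3, 2.3, 0),
    motion_rate_hz = c(1.8, 1.0, 1.4, 0.8, 1.3, 0.9, 3.0, 2.0,
                       0.9, 0.8, 1.4, 1.1, 0.9, 1.6)
  )
  starts <- (seq_len(nrow(tasks)) - 1L) * (bout_s + rest_s)
  bouts <- cbind(start_s = starts, duration_s = bout_s, tasks)
  activity_script(bouts, total_s = max(starts) + bout_s + rest_s)
}

#' Build a subject profile
#'
#' Kinetic and anthropometric parameters of one simulated subject: body
#' mass, resting and peak mass-normalized oxygen uptake, and the on/off
#' time constants of the first-order uptake kinetics.
#'
#' @param mass_kg body mass, kg (> 0).
#' @param vo2_rest resting VO2, mL/kg/min (> 0).
#' @param vo2_peak peak VO2, mL/kg/min (> vo2_rest).
#' @param tau_on,tau_off on-/off-transient time constants, seconds (> 0).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(mass_kg = 76.7, vo2_rest = 5, vo2_peak = 40,
                            tau_on = 30, tau_off = 45) {
  check_scalar(mass_kg, "mass_kg", lower = 0, strict_lower = TRUE)
  check_scalar(vo2_rest, "vo2_rest", lower = 0, strict_lower = TRUE)
  check_scalar(vo2_peak, "vo2_peak", lower = vo2_rest, strict_lower = TRUE)
  check_scalar(tau_on, "tau_on", lower = 0, strict_lower = TRUE)
  check_scalar(tau_off, "tau_off", lower = 0, strict_lower = TRUE)
  structure(list(mass_kg = mass_kg, vo2_rest = vo2_rest, vo2_peak = vo2_peak,
                 tau_on = tau_on, tau_off = tau_off),
            class = "subject_profile")
}

#' Generator configuration
#'
#' Sampling rates and noise levels of the simulated armband + metabolic
#' analyzer. Defaults match the armband hardware: 8 EMG electrodes at
#' 200 Hz (signed 8-bit), IMU at 50 Hz, VO2 reference at 1 Hz.
#'
#' @param seed master seed; all per-stream randomness is derived from it.
#' @param emg_rate,imu_rate,vo2_rate sampling rates, Hz.
#' @param n_emg_channels number of EMG electrodes (>= 1).
#' @param vo2_noise_sd measurement noise of the observed VO2 series,
#'   mL/kg/min.
#' @param accel_noise_sd,gyro_noise_sd IMU additive noise, g and deg/s.
#' @param emg_gain master EMG envelope gain, ADC counts.
#' @param emg_noise_floor instrument noise floor at full rest, ADC counts.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, emg_rate = 200, imu_rate = 50,
                             vo2_rate = 1, n_emg_channels = 8L,
                             vo2_noise_sd = 1.0, accel_noise_sd = 0.05,
                             gyro_noise_sd = 5, emg_gain = 30,
                             emg_noise_floor = 2) {
  check_scalar(emg_rate, "emg_rate", 0, strict_lower = TRUE)
  check_scalar(imu_rate, "imu_rate", 0, strict_lower = TRUE)
  check_scalar(vo2_rate, "vo2_rate", 0, strict_lower = TRUE)
  check_scalar(n_emg_channels, "n_emg_channels", 1)
  check_scalar(vo2_noise_sd, "vo2_noise_sd", 0)
  check_scalar(accel_noise_sd, "accel_noise_sd", 0)
  check_scalar(gyro_noise_sd, "gyro_noise_sd", 0)
  check_scalar(emg_gain, "emg_gain", 0)
  check_scalar(emg_noise_floor, "emg_noise_floor", 0)
  structure(list(seed = as.integer(seed), emg_rate = emg_rate,
                 imu_rate = imu_rate, vo2_rate = vo2_rate,
                 n_emg_channels = as.integer(n_emg_channels),
                 vo2_noise_sd = vo2_noise_sd, accel_noise_sd = accel_noise_sd,
                 gyro_noise_sd = gyro_noise_sd, emg_gain = emg_gain,
                 emg_noise_floor = emg_noise_floor),
            class = "generator_config")
}

# Per-second bout attributes over the whole script: intensity, load,
# motion rate; rest seconds get zeros. `t` is a vector of times (seconds).
script_attributes <- function(script, t) {
  intensity <- numeric(length(t))
  load <- numeric(length(t))
  rate <- numeric(length(t))
  for (i in seq_len(nrow(script$bouts))) {
    b <- script$bouts[i, ]
    sel <- t >= b$start_s & t < b$start_s + b$duration_s
    intensity[sel] <- b$intensity
    load[sel] <- b$load_kg
    rate[sel] <- b$motion_rate_hz
  }
  list(intensity = intensity, load = load, motion_rate = rate)
}
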