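# Per-second statistical feature extraction: 17 statistics over 17 raw
# channels (+ resultants), lag/rolling derived columns, per-second target
# alignment.

STAT_NAMES <- c("sum", "avg", "min", "max", "median", "stdev", "cv", "var",
                "per5", "per10", "per25", "per50", "per75", "per90", "per95",
                "skew", "kurtosis")

IMU_CHANNELS <- c("ax", "ay", "az", "res_acc", "gx", "gy", "gz", "res_gyro")

#' Feature-extraction specification
#'
#' Fixes the statistic set, the raw channel list and the derived-column
#' mode. `standard_290` appends only the one-second lag of the per-second
#' EMGsum mean (290 columns total); `extended_295` appends lag-1 and
#' trailing rolling-mean(3) of the per-second means of the acceleration
#' resultant, gyroscope resultant and EMGsum (295 columns).
#'
#' @param derived_mode `"standard_290"` (default) or `"extended_295"`.
#' @param n_emg_channels number of EMG electrodes (default 8).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(derived_mode = c("standard_290", "extended_295"),
                         n_emg_channels = 8L) {
  derived_mode <- match.arg(derived_mode)
  channels <- c(IMU_CHANNELS, paste0("EMG", seq_len(n_emg_channels)), "EMGsum")
  derived <- if (derived_mode == "standard_290") "EMGsum_lag1"
  else c("Acc_lag1", "Gyro_lag1", "EMGsum_lag1",
         "Acc_mean", "Gyro_mean", "EMGsum_mean")
  structure(list(stat_names = STAT_NAMES, channels = channels,
                 derived_mode = derived_mode, derived = derived),
            class = "feature_spec")
}

#' Feature column names implied by a spec
#'
#' @param spec a [feature_spec()].
#' @return character vector: `<channel>_<stat>` for every channel/statistic
#'   pair, followed by the derived columns.
#' @export
feature_names <- function(spec = feature_spec()) {
  base <- as.vector(t(outer(spec$channels, spec$stat_names, paste, sep = "_")))
  c(base, spec$derived)
}

#' The 17 windowed statistics of one numeric sequence
#'
#' Returns sum, mean, min, max, median, standard deviation, coefficient of
#' variation, variance, the 5/10/25/50/75/90/95th percentiles, skewness and
#' excess kurtosis. Conventions: population (biased) moments; percentiles
#' by linear interpolation between order statistics; zero-variance windows
#' return stdev = var = cv = skew = kurtosis = 0; cv = stdev/mean with 0
#' when the mean is exactly 0.
#'
#' @param values numeric vector, length >= 1.
#' @return named numeric vector of length 17.
#' @export
window_stats <- function(values) {
  if (length(values) < 1L) stop_user("window_stats needs a non-empty sequence")
  drop(window_stats_matrix(matrix(as.numeric(values), ncol = 1L)))
}

# Vectorized core: m is (samples-per-window x n-windows); returns a
# 17 x n matrix, one column of statistics per window.
window_stats_matrix <- function(m) {
  r <- nrow(m); n <- ncol(m)
  s <- if (r == 1L) m else apply(m, 2L, sort, method = "radix")
  if (is.null(dim(s))) s <- matrix(s, nrow = r)
  qs <- function(p) {            # type-7 interpolated percentile per column
    h <- (r - 1) * p
    lo <- floor(h) + 1
    fr <- h - floor(h)
    if (lo >= r) s[r, ] else s[lo, ] + fr * (s[lo + 1L, ] - s[lo, ])
  }
  mu <- colMeans(m)
  d <- m - rep(mu, each = r)
  m2 <- colMeans(d * d)
  m3 <- colMeans(d * d * d)
  m4 <- colMeans(d * d * d * d)
  stdev <- sqrt(m2)
  zerovar <- m2 <= 0
  skew <- ifelse(zerovar, 0, m3 / ifelse(zerovar, 1, m2^1.5))
  kurt <- ifelse(zerovar, 0, m4 / ifelse(zerovar, 1, m2^2) - 3)
  cv <- ifelse(mu == 0, 0, stdev / mu)
  out <- rbind(sum = colSums(m), avg = mu, min = s[1L, ], max = s[r, ],
               median = qs(0.5), stdev = stdev, cv = cv, var = m2,
               per5 = qs(0.05), per10 = qs(0.10), per25 = qs(0.25),
               per50 = qs(0.50), per75 = qs(0.75), per90 = qs(0.90),
               per95 = qs(0.95), skew = skew, kurtosis = kurt)
  out[STAT_NAMES, , drop = FALSE]
}

#' Per-sample resultant channels
#'
#' Augments the raw axes with the Euclidean acceleration resultant
#' `res_acc = sqrt(ax^2 + ay^2 + az^2)` (per 50 Hz sample), the gyroscope
#' resultant `res_gyro`, and `EMGsum`, the per-200 Hz-sample sum of
#' absolute EMG channel values (a signed raw sum would cancel to ~0).
#'
#' @param accel n x 3 acceleration matrix (g).
#' @param gyro n x 3 angular-velocity matrix (deg/s).
#' @param emg n x 8 integer EMG matrix.
#' @return list with numeric vectors `res_acc`, `res_gyro`, `emgsum`.
#' @export
compute_resultants <- function(accel, gyro, emg) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro); emg <- as.matrix(emg)
  list(res_acc = sqrt(rowSums(accel^2)),
       res_gyro = sqrt(rowSums(gyro^2)),
       emgsum = rowSums(abs(emg)))
}

# trailing mean over up to `w` most recent values (partial at the start)
rolling_mean_trailing <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  lo <- pmax(seq_len(n) - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
}

#' Build the per-second feature table of one recording
#'
#' Applies [window_stats()] to each of the 17 channels over every
#' non-overlapping one-second window \[k, k+1) (50 samples per IMU
#' channel, 200 per EMG channel), yielding 289 statistical columns, then
#' appends the derived lag/rolling columns of the [feature_spec()] and the
#' 1 Hz VO2 target. The first row of each recording is dropped because the
#' lag feature is undefined there.
#'
#' @param rec a trimmed `sensor_recording` (whole seconds; see
#'   [trim_to_overlap()]).
#' @param spec a [feature_spec()].
#' @return `data.table` with the feature columns (in spec order) followed
#'   by `target` (mL/kg/min), optional `target_truth`, `subject_id`,
#'   optional `label`, and `second` (0-based window index).
#' @export
build_feature_table <- function(rec, spec = feature_spec()) {
  stopifnot(inherits(rec, "sensor_recording"), inherits(spec, "feature_spec"))
  S <- nrow(rec$vo2$values)
  if (S < 3L) stop_user("recording shorter than 3 s")
  imu_r <- rec$accel$rate
  emg_r <- rec$emg$rate
  if (nrow(rec$accel$values) < S * imu_r || nrow(rec$emg$values) < S * emg_r)
    stop_user("streams do not cover ", S, " whole seconds; trim_to_overlap first")
  res <- compute_resultants(rec$accel$values, rec$gyro$values, rec$emg$values)
  imu_take <- seq_len(S * imu_r)
  emg_take <- seq_len(S * emg_r)
  chans <- c(
    list(ax = rec$accel$values[imu_take, 1L], ay = rec$accel$values[imu_take, 2L],
         az = rec$accel$values[imu_take, 3L], res_acc = res$res_acc[imu_take],
         gx = rec$gyro$values[imu_take, 1L], gy = rec$gyro$values[imu_take, 2L],
         gz = rec$gyro$values[imu_take, 3L], res_gyro = res$res_gyro[imu_take]),
    stats::setNames(lapply(seq_len(ncol(rec$emg$values)), function(j)
      as.numeric(rec$emg$values[emg_take, j])),
      paste0("EMG", seq_len(ncol(rec$emg$values)))),
    list(EMGsum = res$emgsum[emg_take])
  )
  if (!identical(names(chans), spec$channels))
    stop_user("recording channels do not match the feature spec")
  blocks <- lapply(names(chans), function(nm) {
    x <- chans[[nm]]
    rate <- length(x) / S
    st <- t(window_stats_matrix(matrix(x, nrow = rate, ncol = S)))
    colnames(st) <- paste(nm, STAT_NAMES, sep = "_")
    st
  })
  feat <- do.call(cbind, blocks)
  lag1 <- function(v) c(NA_real_, v[-length(v)])
  derived <- switch(spec$derived_mode,
    standard_290 = cbind(EMGsum_lag1 = lag1(feat[, "EMGsum_avg"])),
    extended_295 = cbind(
      Acc_lag1 = lag1(feat[, "res_acc_avg"]),
      Gyro_lag1 = lag1(feat[, "res_gyro_avg"]),
      EMGsum_lag1 = lag1(feat[, "EMGsum_avg"]),
      Acc_mean = rolling_mean_trailing(feat[, "res_acc_avg"], 3L),
      Gyro_mean = rolling_mean_trailing(feat[, "res_gyro_avg"], 3L),
      EMGsum_mean = rolling_mean_trailing(feat[, "EMGsum_avg"], 3L)))
  tab <- data.table::as.data.table(cbind(feat, derived))
  tab[, target := as.numeric(rec$vo2$values[seq_len(S), 1L])]
  if (!is.null(rec$vo2_truth)) tab[, target_truth := rec$vo2_truth[seq_len(S)]]
  tab[, subject_id := rec$subject_id]
  if (!is.null(rec$labels)) tab[, label := rec$labels[seq_len(S)]]
  tab[, second := seq_len(S) - 1L]
  tab <- tab[-1L]                      # lag feature undefined in window 0
  stopifnot(!anyNA(tab[, feature_names(spec), with = FALSE]))
  tab[]
}

#' Build and stack feature tables for a cohort
#'
#' @param cohort list of `sensor_recording`.
#' @param spec a [feature_spec()].
#' @return one stacked `data.table` (one block of rows per subject).
#' @export
build_cohort_features <- function(cohort, spec = feature_spec()) {
  data.table::rbindlist(lapply(cohort, build_feature_table, spec = spec),
                        use.names = TRUE)
}

# Names of non-feature metadata columns in a feature table.
META_COLS <- c("target", "target_truth", "subject_id", "label", "second")

#' Feature columns present in a feature table
#'
#' @param table a feature table.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) setdiff(names(table), META_COLS)

#' Restrict features to a sensor combination
#'
#' @param cols character vector of candidate feature names.
#' @param combination `"imu+emg"`, `"imu"` or `"emg"`.
#' @return the subset of `cols` derived from the chosen sensors: IMU
#'   covers the accelerometer/gyroscope axes, their resultants and the
#'   Acc/Gyro derived columns; EMG covers EMG1..EMG8, EMGsum and the
#'   EMGsum derived columns.
#' @export
sensor_columns <- function(cols, combination = c("imu+emg", "imu", "emg")) {
  combination <- match.arg(combination)
  is_emg <- grepl("^EMG", cols)
  is_imu <- grepl("^(ax|ay|az|gx|gy|gz|res_acc|res_gyro|Acc|Gyro)_", cols)
  switch(combination,
         "imu+emg" = cols[is_emg | is_imu],
         "imu" = cols[is_imu],
         "emg" = cols[is_emg])
}
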