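# Stream containers, CSV stream input/output, validation, time alignment.

#' Build a channel stream
#'
#' A uniformly sampled multichannel stream: `values` is an n x width
#' matrix sampled at `rate` Hz starting at `t0` seconds (recording-relative
#' time). Width is 1 for VO2, 3 for accelerometer/gyroscope, 8 for EMG.
#'
#' @param name stream identifier.
#' @param rate sampling rate, Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @param values numeric matrix (n x width).
#' @return An object of class `channel_stream`.
#' @export
channel_stream <- function(name, rate, t0, values) {
  check_scalar(rate, "rate", 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop_user("stream '", name, "' is empty")
  structure(list(name = name, rate = rate, t0 = t0, values = values),
            class = "channel_stream")
}

stream_times <- function(s) s$t0 + (seq_len(nrow(s$values)) - 1L) / s$rate

# half-open span [t0, t0 + n/rate)
stream_span <- function(s) c(s$t0, s$t0 + nrow(s$values) / s$rate)

#' Build a sensor recording
#'
#' One subject's synchronized raw streams: 8-channel EMG (200 Hz, signed
#' 8-bit integers), accelerometer and gyroscope (50 Hz), and the 1 Hz VO2
#' reference (mL/kg/min), plus body mass and optional per-second activity
#' labels and noiseless ground-truth VO2 (carried by simulated recordings).
#'
#' @param subject_id identifier.
#' @param mass_kg body mass, kg (> 0).
#' @param emg,accel,gyro,vo2 [channel_stream()] objects.
#' @param vo2_truth optional noiseless VO2 vector aligned with `vo2`.
#' @param labels optional character vector of per-second activity tags.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(subject_id, mass_kg, emg, accel, gyro, vo2,
                             vo2_truth = NULL, labels = NULL) {
  check_scalar(mass_kg, "mass_kg", 0, strict_lower = TRUE)
  for (s in list(emg, accel, gyro, vo2))
    if (!inherits(s, "channel_stream")) stop_user("streams must be channel_stream")
  rec <- structure(list(subject_id = subject_id, mass_kg = mass_kg,
                        emg = emg, accel = accel, gyro = gyro, vo2 = vo2,
                        vo2_truth = vo2_truth, labels = labels),
                   class = "sensor_recording")
  validate_recording(rec)
  rec
}

#' @export
print.sensor_recording <- function(x, ...) {
  sp <- stream_span(x$vo2)
  cat("<sensor_recording>", x$subject_id, "|", x$mass_kg, "kg |",
      sprintf("%.0f s VO2 span | EMG %d x %d @ %g Hz | IMU @ %g Hz\n",
              diff(sp), nrow(x$emg$values), ncol(x$emg$values), x$emg$rate,
              x$accel$rate))
  invisible(x)
}

#' Validate a recording against the stream invariants
#'
#' Checks stream widths, the signed 8-bit EMG range (naming the first
#' offending sample), and positive rates. Called by constructors and by
#' the CLI `validate` subcommand.
#'
#' @param rec a `sensor_recording`.
#' @return `rec`, invisibly; errors describe the violated invariant.
#' @export
validate_recording <- function(rec) {
  if (ncol(rec$accel$values) != 3L) stop_user("accel stream must have 3 axes")
  if (ncol(rec$gyro$values) != 3L) stop_user("gyro stream must have 3 axes")
  if (ncol(rec$vo2$values) != 1L) stop_user("vo2 stream must have 1 channel")
  e <- rec$emg$values
  bad <- which(e < -128 | e > 127 | e != round(e))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(e))
    stop_user("EMG value out of signed 8-bit range [-128, 127] at sample ",
              idx[1L], ", channel ", idx[2L], " (value ", e[bad[1L]], ")")
  }
  if (!is.null(rec$vo2_truth) &&
      length(rec$vo2_truth) != nrow(rec$vo2$values))
    stop_user("vo2_truth length does not match vo2 stream")
  invisible(rec)
}

# ---- CSV stream dialect --------------------------------------------------
# Header row; first column `t` = seconds from recording start, printed with
# 6 decimal places; remaining columns are channel values. One file per
# modality.

write_stream_csv <- function(s, path, integer_values = FALSE) {
  dt <- data.table::as.data.table(s$values)
  tcol <- sprintf("%.6f", stream_times(s))
  dt <- cbind(data.table::data.table(t = tcol), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

read_stream_csv <- function(path, name, expected_width = NULL) {
  if (!file.exists(path)) stop_user("stream file missing: ", path)
  dt <- data.table::fread(path)
  if (!"t" %in% names(dt)) stop_user(path, ": no `t` column")
  t <- dt$t
  if (nrow(dt) < 2L) stop_user(path, ": need at least 2 samples")
  if (any(diff(t) <= 0)) stop_user(path, ": timestamps not strictly increasing")
  dts <- diff(t)
  step <- stats::median(dts)
  if (any(abs(dts - step) > 0.01 * step))
    stop_user(path, ": non-uniform sampling beyond 1% jitter")
  rate <- 1 / step
  # snap to a clean nominal rate when within rounding error
  if (abs(rate - round(rate)) < 0.01 * rate) rate <- round(rate)
  vals <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.null(expected_width) && ncol(vals) != expected_width)
    stop_user(path, ": expected ", expected_width, " channels, found ", ncol(vals))
  channel_stream(name, rate, t[1L], vals)
}

#' Write one recording's streams to CSV files
#'
#' @param rec a `sensor_recording`.
#' @param dir output directory.
#' @return named list of written paths (emg, accel, gyro, vo2, labels).
#' @export
write_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, rec$subject_id)
  paths <- list(emg = paste0(base, "_emg.csv"),
                accel = paste0(base, "_accel.csv"),
                gyro = paste0(base, "_gyro.csv"),
                vo2 = paste0(base, "_vo2.csv"))
  write_stream_csv(rec$emg, paths$emg, integer_values = TRUE)
  write_stream_csv(rec$accel, paths$accel)
  write_stream_csv(rec$gyro, paths$gyro)
  vo2s <- rec$vo2
  if (!is.null(rec$vo2_truth))
    vo2s$values <- cbind(vo2s$values, vo2_truth = rec$vo2_truth)
  write_stream_csv(vo2s, paths$vo2)
  if (!is.null(rec$labels)) {
    paths$labels <- paste0(base, "_labels.csv")
    data.table::fwrite(data.table::data.table(
      t = sprintf("%.6f", stream_times(rec$vo2)), label = rec$labels),
      paths$labels)
  }
  paths
}

#' Load one recording from a manifest entry
#'
#' @param entry list with fields `id`, `mass_kg` and file paths `emg`,
#'   `accel`, `gyro`, `vo2` (and optionally `labels`).
#' @return A validated `sensor_recording`.
#' @export
load_recording <- function(entry) {
  for (f in c("id", "mass_kg", "emg", "accel", "gyro", "vo2"))
    if (is.null(entry[[f]])) stop_user("manifest entry missing field: ", f)
  emg <- read_stream_csv(entry$emg, "emg")
  accel <- read_stream_csv(entry$accel, "accel", 3L)
  gyro <- read_stream_csv(entry$gyro, "gyro", 3L)
  vo2raw <- read_stream_csv(entry$vo2, "vo2")
  vo2_truth <- NULL
  if ("vo2_truth" %in% colnames(vo2raw$values)) {
    vo2_truth <- as.numeric(vo2raw$values[, "vo2_truth"])
    vo2raw$values <- vo2raw$values[, setdiff(colnames(vo2raw$values), "vo2_truth"),
                                   drop = FALSE]
  }
  labels <- NULL
  if (!is.null(entry$labels) && file.exists(entry$labels))
    labels <- data.table::fread(entry$labels)$label
  sensor_recording(entry$id, as.numeric(entry$mass_kg),
                   emg = emg, accel = accel, gyro = gyro, vo2 = vo2raw,
                   vo2_truth = vo2_truth, labels = labels)
}

#' Trim all streams to their common time span
#'
#' Cuts every stream to the intersection of the four spans, then truncates
#' to a whole number of seconds so an integer number of one-second windows
#' \[k, k+1) exists. After trimming, `count(vo2) == floor(span)` and
#' `count(emg) == count(vo2) * emg_rate`.
#'
#' @param rec a `sensor_recording`.
#' @return the trimmed `sensor_recording`.
#' @export
trim_to_overlap <- function(rec) {
  spans <- lapply(list(rec$emg, rec$accel, rec$gyro, rec$vo2), stream_span)
  a <- max(vapply(spans, `[`, numeric(1), 1L))
  b <- min(vapply(spans, `[`, numeric(1), 2L))
  if (b - a <= 1e-9) stop_user("streams have empty time overlap")
  span_s <- floor(b - a + 1e-9)
  if (span_s < 1) stop_user("common span shorter than one second")
  cut <- function(s) {
    t <- stream_times(s)
    keep <- t >= a - 1e-9 & t < a + span_s - 1e-9
    channel_stream(s$name, s$rate, a, s$values[keep, , drop = FALSE])
  }
  keep_vo2 <- stream_times(rec$vo2) >= a - 1e-9 &
    stream_times(rec$vo2) < a + span_s - 1e-9
  out <- rec
  out$emg <- cut(rec$emg)
  out$accel <- cut(rec$accel)
  out$gyro <- cut(rec$gyro)
  out$vo2 <- cut(rec$vo2)
  if (!is.null(rec$vo2_truth)) out$vo2_truth <- rec$vo2_truth[keep_vo2]
  if (!is.null(rec$labels)) out$labels <- rec$labels[keep_vo2]
  validate_recording(out)
  out
}
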