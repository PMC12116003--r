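# Task-level oxygen cost: per-task means, unit conversion, column
# statistics, measured-vs-estimated comparison, work-severity banding.

#' Summarize the oxygen cost of one task
#'
#' Mean VO2 over the task span in mL/kg/min and its absolute equivalent
#' `L/min = mean * mass / 1000`.
#'
#' @param vo2_series 1 Hz VO2 series, mL/kg/min (non-empty).
#' @param mass_kg body mass, kg (> 0).
#' @return list with `mean_mlkgmin`, `mean_lmin`, `duration_s`.
#' @export
summarize_task <- function(vo2_series, mass_kg) {
  if (!length(vo2_series)) stop_user("empty VO2 series")
  check_scalar(mass_kg, "mass_kg", 0, strict_lower = TRUE)
  m <- mean(vo2_series)
  list(mean_mlkgmin = m, mean_lmin = m * mass_kg / 1000,
       duration_s = length(vo2_series))
}

#' Mean and sample standard deviation of a per-subject column
#'
#' @param values numeric vector, one value per subject (n >= 2).
#' @return list with `mean` and `sd` (n - 1 denominator).
#' @export
column_statistics <- function(values) {
  if (length(values) < 2L) stop_user("SD undefined for fewer than 2 subjects")
  list(mean = mean(values), sd = sd(values))
}

#' Compare measured and estimated per-subject oxygen cost
#'
#' One-way two-group ANOVA (F with df 1 and 2n - 2) on the two vectors of
#' per-subject means, plus the paired difference column statistics and,
#' for completeness, the paired t-test.
#'
#' @param measured,estimated per-subject mean VO2, mL/kg/min, equal length
#'   (n >= 2).
#' @return An object of class `group_comparison`: group means/SDs,
#'   difference mean/SD (measured - estimated), `F`, `p` (from the F
#'   distribution), and `p_paired` from the paired t-test.
#' @export
compare_groups <- function(measured, estimated) {
  n <- length(measured)
  if (length(estimated) != n) stop_user("groups must have equal length")
  if (n < 2L) stop_user("need at least 2 subjects per group")
  gm <- mean(measured); ge <- mean(estimated)
  grand <- mean(c(measured, estimated))
  ssb <- n * ((gm - grand)^2 + (ge - grand)^2)
  ssw <- sum((measured - gm)^2) + sum((estimated - ge)^2)
  df1 <- 1L; df2 <- 2L * n - 2L
  Fstat <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(Fstat)) 0 else pf(Fstat, df1, df2, lower.tail = FALSE)
  d <- measured - estimated
  p_paired <- if (sd(d) == 0) { if (mean(d) == 0) 1 else 0 } else
    pt(abs(mean(d)) / (sd(d) / sqrt(n)), n - 1L, lower.tail = FALSE) * 2
  structure(list(group_means = c(measured = gm, estimated = ge),
                 group_sds = c(measured = sd(measured), estimated = sd(estimated)),
                 mean_difference = mean(d), sd_difference = sd(d),
                 F = Fstat, df = c(df1, df2), p = p, p_paired = p_paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> measured %.2f +/- %.2f vs estimated %.2f +/- %.2f\n",
              x$group_means[1], x$group_sds[1], x$group_means[2], x$group_sds[2]))
  cat(sprintf("  difference %.2f +/- %.2f | F(%d, %d) = %.4g, p = %.4f (paired t p = %.4f)\n",
              x$mean_difference, x$sd_difference, x$df[1], x$df[2],
              x$F, x$p, x$p_paired))
  invisible(x)
}

#' Build the per-subject task summary table
#'
#' One row per subject mirroring the standard task-cost layout: mass,
#' measured and estimated mean VO2 in both units, and their difference
#' (measured - estimated, mL/kg/min).
#'
#' @param subject_ids identifiers.
#' @param mass_kg per-subject masses.
#' @param measured,estimated per-subject 1 Hz series as lists, or numeric
#'   vectors of precomputed means (mL/kg/min).
#' @return data.frame of class `task_summary`.
#' @export
task_summary <- function(subject_ids, mass_kg, measured, estimated) {
  mm <- if (is.list(measured))
    vapply(measured, function(v) mean(v), numeric(1)) else as.numeric(measured)
  em <- if (is.list(estimated))
    vapply(estimated, function(v) mean(v), numeric(1)) else as.numeric(estimated)
  stopifnot(length(subject_ids) == length(mass_kg),
            length(mm) == length(subject_ids),
            length(em) == length(subject_ids))
  out <- data.frame(subject_id = subject_ids, mass_kg = mass_kg,
                    measured_mlkgmin = mm,
                    measured_lmin = mm * mass_kg / 1000,
                    estimated_mlkgmin = em,
                    estimated_lmin = em * mass_kg / 1000,
                    difference = mm - em)
  class(out) <- c("task_summary", "data.frame")
  out
}

#' Classify absolute oxygen cost into work-severity bands
#'
#' Bands are configuration, not built-in claims: supply a data.frame of
#' ordered, non-overlapping half-open intervals \[lo, hi) with labels.
#' A value on a boundary belongs to the lower band; a value outside all
#' bands returns `"unclassified"`.
#'
#' @param lmin absolute oxygen cost, L/min.
#' @param bands data.frame with columns `lo`, `hi`, `label`; see
#'   [example_severity_bands()] for a documented example configuration.
#' @return character label.
#' @export
classify_severity <- function(lmin, bands) {
  if (is.null(bands) || nrow(as.data.frame(bands)) == 0L) return("unclassified")
  bands <- as.data.frame(bands)
  bands <- bands[order(bands$lo), ]
  if (any(bands$hi <= bands$lo)) stop_user("bands must have hi > lo")
  if (nrow(bands) > 1L && any(bands$lo[-1L] < bands$hi[-nrow(bands)]))
    stop_user("bands overlap")
  for (i in seq_len(nrow(bands)))
    if (lmin >= bands$lo[i] && lmin < bands$hi[i]) return(bands$label[i])
  "unclassified"
}

#' An example work-severity band configuration
#'
#' Illustrative occupational banding of absolute oxygen cost; thresholds
#' are an example configuration for [classify_severity()], not a
#' scientific claim of this package.
#'
#' @return data.frame with `lo`, `hi` (L/min) and `label`.
#' @export
example_severity_bands <- function() {
  data.frame(lo = c(0, 0.5, 1.0, 1.5),
             hi = c(0.5, 1.0, 1.5, 2.0),
             label = c("light", "moderate", "heavy", "very heavy"))
}

#' Bundled scaffold-unit oxygen-cost reference table
#'
#' Per-participant measured and estimated oxygen cost of building one
#' scaffolding unit (ten participants): body mass, mean VO2 in mL/kg/min
#' and L/min for both conditions, and the published difference column
#' (measured - estimated, mL/kg/min). Used by the worked examples and the
#' acceptance checks.
#'
#' @return data.frame with one row per participant.
#' @export
scaffold_unit_reference <- function() {
  path <- system.file("extdata", "scaffold_unit_vo2.csv", package = "wearvo2")
  as.data.frame(data.table::fread(path))
}
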