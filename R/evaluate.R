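# Regression metrics, leave-one-subject-out cross-validation and the
# architecture x sensor-combination comparison harness.

#' Regression metric set
#'
#' MAE, MSE, RMSE, MAPE (percent, excluding zero targets and reporting
#' their count), Pearson correlation r and the coefficient of
#' determination R^2 = 1 - SS_res/SS_tot. `eq5_literal`, the ratio
#' SS_res/SS_tot that a literal reading of some printed formulas yields,
#' is reported alongside for transparency; it is not a correlation.
#'
#' @param y observed series (mL/kg/min).
#' @param yhat predicted series, equal length (>= 2).
#' @return An object of class `metric_set`: named list with `mae`, `mse`,
#'   `rmse`, `mape`, `mape_n_excluded`, `r`, `r2`, `eq5_literal`, `n`.
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_user("y and yhat lengths differ")
  if (length(y) < 2L) stop_user("need at least 2 samples")
  err <- y - yhat
  mse <- mean(err^2)
  mae <- mean(abs(err))
  rmse <- sqrt(mse)
  nz <- y != 0
  mape <- if (any(nz)) 100 * mean(abs(err[nz] / y[nz])) else NA_real_
  sst <- sum((y - mean(y))^2)
  ssr <- sum(err^2)
  r <- if (sd(y) == 0 || sd(yhat) == 0) NA_real_ else cor(y, yhat)
  r2 <- if (sst == 0) NA_real_ else 1 - ssr / sst
  structure(list(mae = mae, mse = mse, rmse = rmse, mape = mape,
                 mape_n_excluded = sum(!nz), r = r, r2 = r2,
                 eq5_literal = if (sst == 0) NA_real_ else ssr / sst,
                 n = length(y)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> n=%d  MAE=%.3f  RMSE=%.3f  MAPE=%s  r=%.3f  R2=%.3f\n",
              x$n, x$mae, x$rmse,
              if (is.na(x$mape)) "NA" else sprintf("%.1f%%", x$mape),
              x$r, x$r2))
  if (x$mape_n_excluded > 0)
    cat("  (", x$mape_n_excluded, "zero-target samples excluded from MAPE )\n")
  invisible(x)
}

metric_row <- function(m) {
  data.frame(mae = m$mae, mse = m$mse, rmse = m$rmse, mape = m$mape,
             r = m$r, r2 = m$r2)
}

#' Leave-one-subject-out folds
#'
#' @param subject_ids vector of distinct subject identifiers (>= 2).
#' @return list of `list(train_ids, test_id)`, one fold per subject: every
#'   subject is test exactly once, train and test are disjoint and their
#'   union is the full id set.
#' @export
loso_folds <- function(subject_ids) {
  ids <- unique(subject_ids)
  if (length(ids) < 2L) stop_user("LOSO needs at least 2 subjects")
  lapply(ids, function(id) list(train_ids = setdiff(ids, id), test_id = id))
}

#' Run leave-one-subject-out cross-validation
#'
#' Per fold: restrict candidate columns to the sensor combination, select
#' features (globally precomputed by default, or per fold in the
#' leakage-safe mode), fit the min-max scaler on training rows only,
#' train the configured recurrent regressor, predict the held-out
#' subject, and compute metrics. Feature selection fitted once on the
#' full corpus reproduces the original pipeline's order of operations and
#' is flagged in the report.
#'
#' @param table stacked cohort feature table from [build_cohort_features()].
#' @param config a [model_config()].
#' @param combination sensor combination: `"imu+emg"`, `"imu"` or `"emg"`.
#' @param leakage_mode `"global"` (selection on the full corpus, as in the
#'   original pipeline) or `"per_fold"` (selection refit on each training
#'   fold).
#' @param r_threshold,mi_threshold selection thresholds.
#' @param target column used for metric computation: `"target"` (observed
#'   VO2) or `"target_truth"` (noiseless ground truth, when present).
#' @param selection optional precomputed `selection_result` to reuse in
#'   global mode.
#' @return An object of class `loso_report`: list with `folds`
#'   (per-fold `metric_set` + predictions), `averaged` (unweighted mean of
#'   fold metrics), `config` snapshot and `kept` feature names.
#' @export
run_loso <- function(table, config = model_config(),
                     combination = c("imu+emg", "imu", "emg"),
                     leakage_mode = c("global", "per_fold"),
                     r_threshold = 0.1, mi_threshold = 0.1,
                     target = c("target", "target_truth"),
                     selection = NULL) {
  combination <- match.arg(combination)
  leakage_mode <- match.arg(leakage_mode)
  target <- match.arg(target)
  table <- data.table::as.data.table(table)
  ids <- unique(table$subject_id)
  folds <- loso_folds(ids)
  candidates <- sensor_columns(feature_columns(table), combination)
  if (!length(candidates)) stop_user("no candidate features for ", combination)
  if (leakage_mode == "global" && is.null(selection))
    selection <- select_features(table, r_threshold, mi_threshold,
                                 candidate_cols = candidates)
  fold_res <- lapply(folds, function(fold) {
    tr <- table$subject_id %in% fold$train_ids
    te <- table$subject_id == fold$test_id
    sel <- if (leakage_mode == "per_fold")
      select_features(table[tr], r_threshold, mi_threshold,
                      candidate_cols = candidates)
    else selection
    keep <- intersect(kept_features(sel), candidates)
    if (!length(keep))
      stop_user("no features kept for ", combination, " at |r| > ",
                r_threshold, ", MI > ", mi_threshold)
    scaler <- fit_scaler(table, rows_mask = which(tr), cols = keep)
    scaled <- apply_scaler(scaler, table)
    trs <- reshape_for_sequence(scaled[which(tr)], config$seq_len, keep)
    tes <- reshape_for_sequence(scaled[which(te)], config$seq_len, keep)
    model <- build_model(config, length(keep))
    model <- train_model(model, trs$X, trs$y, trs$subjects)
    pred <- predict(model, tes$X)
    y_ref <- if (target == "target_truth" && !is.null(tes$y_truth))
      tes$y_truth else tes$y
    list(held_out_subject = fold$test_id,
         metrics = compute_metrics(y_ref, pred),
         predictions = data.frame(subject_id = fold$test_id,
                                  y = tes$y,
                                  y_truth = if (is.null(tes$y_truth)) NA_real_
                                  else tes$y_truth,
                                  yhat = pred),
         kept = keep, model = model)
  })
  fold_tab <- do.call(rbind, lapply(fold_res, function(f)
    cbind(data.frame(held_out = f$held_out_subject), metric_row(f$metrics))))
  avg <- as.list(colMeans(fold_tab[, -1L]))
  structure(list(folds = fold_res, fold_table = fold_tab, averaged = avg,
                 config = list(arch = config$arch,
                               combination = combination,
                               leakage_mode = leakage_mode,
                               seq_len = config$seq_len,
                               target = target),
                 kept = if (leakage_mode == "global")
                   kept_features(selection) else NULL),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("<loso_report> %s | %s | selection: %s | %d folds\n",
              toupper(x$config$arch), x$config$combination,
              x$config$leakage_mode, nrow(x$fold_table)))
  print(x$fold_table, row.names = FALSE, digits = 4)
  cat(sprintf("averaged: MAE=%.3f RMSE=%.3f r=%.3f R2=%.3f\n",
              x$averaged$mae, x$averaged$rmse, x$averaged$r, x$averaged$r2))
  invisible(x)
}

#' Serialize a LOSO report as CSV
#'
#' One row per fold plus an `average` row (unweighted fold mean).
#'
#' @param report a `loso_report`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_loso_report <- function(report, path) {
  avg <- cbind(data.frame(held_out = "average"),
               as.data.frame(report$averaged))
  data.table::fwrite(rbind(report$fold_table, avg), path)
  invisible(path)
}

#' Architecture x sensor-combination comparison harness
#'
#' Runs LOSO for every architecture in `archs` crossed with every sensor
#' combination in `combinations` (nine reports by default) on one shared
#' cohort table and seed.
#'
#' @param table stacked cohort feature table.
#' @param archs architectures to compare.
#' @param combinations sensor combinations to compare.
#' @param base_config `model_config` template; its `arch` is overridden.
#' @param ... further arguments passed to [run_loso()].
#' @return list with `grid` (one row per run: arch, combination, averaged
#'   metrics) and `reports` (the underlying `loso_report`s).
#' @export
compare_models <- function(table, archs = c("lstm", "bilstm", "gru"),
                           combinations = c("imu+emg", "imu", "emg"),
                           base_config = model_config(), ...) {
  runs <- list()
  rows <- list()
  for (comb in combinations) for (arch in archs) {
    cfg <- base_config
    cfg$arch <- arch
    rep <- run_loso(table, cfg, combination = comb, ...)
    key <- paste(comb, arch, sep = "/")
    runs[[key]] <- rep
    rows[[key]] <- cbind(data.frame(combination = comb, arch = arch),
                         as.data.frame(rep$averaged))
  }
  list(grid = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = runs)
}

#' Evaluate a trained model on an unseen recording
#'
#' No refitting: the stored selection (kept columns) and scaler from
#' training are applied as-is to the unseen feature table.
#'
#' @param model a trained `vo2_model`.
#' @param table feature table of the unseen recording.
#' @param scaler the `scaler_state` fitted on training data.
#' @param cols the kept feature columns used at training time.
#' @return list with `metrics` (a `metric_set`) and `predictions`
#'   (per-second data.frame).
#' @export
unseen_evaluation <- function(model, table, scaler, cols) {
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols))
    stop_user("unseen table lacks trained feature columns: ",
              paste(utils::head(missing_cols, 3L), collapse = ", "))
  scaled <- apply_scaler(scaler, table)
  rs <- reshape_for_sequence(scaled, model$config$seq_len, cols)
  pred <- predict(model, rs$X)
  list(metrics = compute_metrics(rs$y, pred),
       predictions = data.frame(subject_id = rs$subjects, y = rs$y,
                                yhat = pred))
}
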