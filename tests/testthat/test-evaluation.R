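# Metrics, LOSO folds and the cross-validation driver.

test_that("compute_metrics reproduces hand-worked examples", {
  perfect <- compute_metrics(c(5, 7, 9), c(5, 7, 9))
  expect_equal(perfect$mae, 0); expect_equal(perfect$mse, 0)
  expect_equal(perfect$rmse, 0); expect_equal(perfect$mape, 0)
  expect_equal(perfect$r, 1); expect_equal(perfect$r2, 1)

  m <- compute_metrics(c(0, 2), c(1, 1))
  expect_equal(m$mae, 1); expect_equal(m$mse, 1); expect_equal(m$rmse, 1)
  expect_equal(m$r2, 0)                       # SS_res = SS_tot = 2
  expect_equal(m$mape, 50)                    # y = 0 excluded
  expect_equal(m$mape_n_excluded, 1L)

  y <- c(4, 8, 15, 16, 23)
  null <- compute_metrics(y, rep(mean(y), 5))
  expect_equal(null$r2, 0)
  expect_error(compute_metrics(1:3, 1:4), "lengths differ")
})

test_that("metric identities hold and a brute-force oracle agrees on 1000 random pairs", {
  set.seed(500)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    y <- rnorm(n, 12, 4)
    yhat <- y + rnorm(n, 0, sample(c(0.1, 1, 3), 1))
    m <- compute_metrics(y, yhat)
    # identities
    expect_equal(m$rmse^2, m$mse, tolerance = 1e-9)
    expect_lte(m$mae, m$rmse + 1e-12)
    # independent re-implementation
    expect_equal(m$mse, sum((y - yhat)^2) / n, tolerance = 1e-9)
    expect_equal(m$mae, sum(abs(y - yhat)) / n, tolerance = 1e-9)
    expect_equal(m$mape, 100 / n * sum(abs((y - yhat) / y)), tolerance = 1e-9)
    expect_equal(m$r,
                 sum((y - mean(y)) * (yhat - mean(yhat))) /
                   sqrt(sum((y - mean(y))^2) * sum((yhat - mean(yhat))^2)),
                 tolerance = 1e-9)
    expect_equal(m$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-9)
    expect_equal(m$eq5_literal, sum((yhat - y)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-9)
  }
})

test_that("r^2 approximates R^2 on linear fits", {
  set.seed(77)
  x <- rnorm(300)
  y <- 2 + 3 * x + rnorm(300)
  yhat <- fitted(lm(y ~ x))
  m <- compute_metrics(y, yhat)
  expect_equal(m$r^2, m$r2, tolerance = 1e-9)   # exact for least squares
})

test_that("LOSO folds partition the subjects exactly, exhaustively for n <= 6", {
  expect_length(loso_folds(sprintf("P%d", 1:10)), 10L)
  two <- loso_folds(c("a", "b"))
  expect_equal(two[[1]]$train_ids, "b")
  expect_equal(two[[2]]$train_ids, "a")
  expect_error(loso_folds("solo"), "at least 2")
  for (n in 2:6) {
    ids <- sprintf("S%02d", seq_len(n))
    folds <- loso_folds(sample(rep(ids, 3)))   # duplicated, shuffled input
    expect_length(folds, n)
    tests <- vapply(folds, `[[`, character(1), "test_id")
    expect_setequal(tests, ids)
    for (f in folds) {
      expect_length(intersect(f$train_ids, f$test_id), 0L)
      expect_setequal(c(f$train_ids, f$test_id), ids)
    }
  }
})

test_that("run_loso holds each subject out once and keeps test rows away from fitting", {
  tab <- tiny_features()
  rep <- run_loso(tab, fast_config(), combination = "imu+emg")
  expect_s3_class(rep, "loso_report")
  expect_equal(nrow(rep$fold_table), 3L)
  expect_setequal(rep$fold_table$held_out, unique(tab$subject_id))
  # averaged metrics are the unweighted fold means
  expect_equal(rep$averaged$rmse, mean(rep$fold_table$rmse))
  expect_equal(rep$averaged$r, mean(rep$fold_table$r))
  # fold predictions cover exactly the held-out subject's windows
  for (f in rep$folds)
    expect_true(all(f$predictions$subject_id == f$held_out_subject))
})

test_that("the scaler never sees held-out rows: extreme test subjects escape [0,1]", {
  tab <- data.table::as.data.table(tiny_features())
  # inflate one subject far outside the others' feature range
  target_cols <- c("res_acc_avg", "EMGsum_avg")
  out <- data.table::copy(tab)
  for (cn in target_cols)
    out[subject_id == "S03", (cn) := out[subject_id == "S03"][[cn]] * 50 + 1000]
  sel_cols <- target_cols
  scaler <- fit_scaler(out, which(out$subject_id != "S03"), sel_cols)
  scaled <- apply_scaler(scaler, out)
  expect_true(all(scaled[scaled$subject_id != "S03"][[sel_cols[1]]] <= 1 + 1e-12))
  expect_true(all(scaled[scaled$subject_id == "S03"][[sel_cols[1]]] > 1))
})

test_that("emg-only runs use exactly the EMG-derived columns", {
  tab <- tiny_features()
  rep <- run_loso(tab, fast_config(), combination = "emg",
                  r_threshold = 0, mi_threshold = 0)
  expect_true(all(grepl("^EMG", rep$kept)))
})

test_that("the comparison harness emits the full architecture x sensor grid", {
  tab <- tiny_features()
  cmp <- compare_models(tab, archs = c("lstm", "bilstm", "gru"),
                        combinations = c("imu+emg", "imu", "emg"),
                        base_config = fast_config())
  expect_equal(nrow(cmp$grid), 9L)
  expect_length(cmp$reports, 9L)
  expect_setequal(unique(cmp$grid$arch), c("lstm", "bilstm", "gru"))
  expect_setequal(unique(cmp$grid$combination), c("imu+emg", "imu", "emg"))
})

test_that("unseen evaluation reuses the trained scaler and errors on missing columns", {
  tab <- tiny_features()
  keep <- c("res_acc_avg", "EMGsum_avg", "az_avg")
  scaler <- fit_scaler(tab, cols = keep)
  scaled <- apply_scaler(scaler, tab)
  rs <- reshape_for_sequence(scaled, 1L, keep)
  m <- train_model(build_model(fast_config(), length(keep)),
                   rs$X, rs$y, rs$subjects)
  res <- unseen_evaluation(m, tab, scaler, keep)
  # unseen = training data reproduces resubstitution metrics
  resub <- compute_metrics(rs$y, predict(m, rs$X))
  expect_equal(res$metrics$rmse, resub$rmse, tolerance = 1e-12)
  expect_equal(nrow(res$predictions), nrow(tab))
  bad <- data.table::copy(data.table::as.data.table(tab))
  bad[, res_acc_avg := NULL]
  expect_error(unseen_evaluation(m, bad, scaler, keep), "lacks")
})

test_that("LOSO reports serialize with an average row", {
  tab <- tiny_features()
  rep <- run_loso(tab, fast_config(), combination = "imu")
  path <- withr::local_tempfile(fileext = ".csv")
  write_loso_report(rep, path)
  back <- data.table::fread(path)
  expect_equal(nrow(back), 4L)
  expect_equal(back$held_out[4], "average")
  expect_equal(back$rmse[4], mean(back$rmse[1:3]), tolerance = 1e-9)
})
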