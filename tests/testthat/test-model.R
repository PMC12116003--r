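# Recurrent regressors: parameter counts, gradients, training contracts.

test_that("parameter counts follow the gate arithmetic", {
  d <- 7L; h <- 5L
  for (arch in c("lstm", "gru")) {
    cfg <- model_config(arch, recurrent_units = h, n_recurrent_layers = 1L,
                        dense_units = 3L)
    m <- build_model(cfg, d)
    G <- if (arch == "gru") 3L else 4L
    layer1 <- sum(vapply(grep("^rnn1\\.", names(m$weights), value = TRUE),
                         function(nm) length(m$weights[[nm]]), integer(1)))
    expect_equal(layer1, G * (d * h + h^2 + h))
  }
  # bidirectional doubles each layer exactly
  uni <- build_model(model_config("lstm", recurrent_units = h,
                                  n_recurrent_layers = 1L, dense_units = 3L), d)
  bi <- build_model(model_config("bilstm", recurrent_units = h,
                                 n_recurrent_layers = 1L, dense_units = 3L), d)
  rec_params <- function(m) sum(vapply(grep("^rnn", names(m$weights),
                                            value = TRUE),
                                       function(nm) length(m$weights[[nm]]),
                                       integer(1)))
  expect_equal(rec_params(bi), 2L * rec_params(uni))
  expect_gte(count_params(bi), count_params(uni))
  expect_error(model_config("transformer"), "arg")
})

test_that("analytic gradients match numerical differentiation for every architecture", {
  set.seed(1)
  for (arch in c("lstm", "bilstm", "gru")) {
    cfg <- model_config(arch, recurrent_units = 4L, dense_units = 5L,
                        dropout = 0, seq_len = 3L, seed = 3L)
    m <- build_model(cfg, 3L)
    X <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
    y <- rnorm(5)
    fw <- wearvo2:::net_forward(m$weights, cfg, X, train = FALSE)
    gr <- wearvo2:::net_backward(m$weights, cfg, X, y, fw)
    loss <- function(w)
      mean((y - wearvo2:::net_forward(w, cfg, X, train = FALSE)$yhat)^2)
    for (nm in names(m$weights)) {
      idx <- sample(length(m$weights[[nm]]), min(4L, length(m$weights[[nm]])))
      for (i in idx) {
        wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + 1e-6
        wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - 1e-6
        num <- (loss(wp) - loss(wm)) / 2e-6
        expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("reshape_for_sequence windows rows without crossing subjects", {
  tab <- data.table::data.table(
    f1 = seq_len(25), f2 = rnorm(25),
    target = 100 + seq_len(25),
    subject_id = rep(c("A", "B"), c(13, 12)),
    second = c(seq_len(13), seq_len(12)))
  one <- reshape_for_sequence(tab, 1L, c("f1", "f2"))
  expect_equal(dim(one$X), c(25, 1, 2))
  expect_equal(one$y, tab$target)
  five <- reshape_for_sequence(tab, 5L, c("f1", "f2"))
  # floor(13/5) + floor(12/5) = 2 + 2 samples; leftovers dropped
  expect_equal(dim(five$X)[1], 4L)
  expect_equal(five$subjects, c("A", "A", "B", "B"))
  # each window is consecutive rows of one subject; target = last row
  expect_equal(five$X[1, , 1], 1:5)
  expect_equal(five$X[3, , 1], 14:18)
  expect_equal(five$y, tab$target[c(5, 10, 18, 23)])
  expect_error(reshape_for_sequence(tab, 20L, c("f1", "f2")), "subject")
  # 100 rows, one subject, seq_len 5 -> 20 samples
  big <- data.table::data.table(f1 = rnorm(100), target = rnorm(100),
                                subject_id = "A", second = 1:100)
  expect_equal(dim(reshape_for_sequence(big, 5L, "f1")$X)[1], 20L)
})

test_that("a small network overfits a deterministic linear mapping", {
  set.seed(2)
  x <- matrix(runif(32), 32, 1)
  y <- 3 * x[, 1] - 1
  cfg <- model_config("lstm", recurrent_units = 16L, dense_units = 16L,
                      dropout = 0, max_epochs = 200L, patience = 200L,
                      batch_size = 8L, seed = 5L)
  m <- train_model(build_model(cfg, 1L), x, y)
  expect_lt(min(m$history$train_mse), 1e-2)
})

test_that("early stopping restores the best weights and patience 0 stops immediately", {
  set.seed(4)
  x <- matrix(rnorm(60 * 3), 60, 3)
  y <- x %*% c(1, -2, 0.5) + rnorm(60, 0, 0.1)
  cfg <- model_config("gru", recurrent_units = 8L, dense_units = 8L,
                      max_epochs = 60L, patience = 0L, seed = 9L,
                      batch_size = 16L)
  m <- train_model(build_model(cfg, 3L), x, drop(y))
  v <- m$history$val_mse
  k <- length(v)
  if (k < cfg$max_epochs) {
    # stopped: final epoch failed to improve, all prior epochs improved
    expect_gte(v[k], min(v[seq_len(k - 1)]))
    if (k > 2)
      for (i in 2:(k - 1)) expect_lt(v[i], min(v[seq_len(i - 1)]))
  }
  # best epoch dominates every later epoch
  expect_true(all(v[m$best_epoch] <= v[seq_along(v) >= m$best_epoch]))
  # restored weights reproduce the best validation loss exactly
  expect_equal(min(v), v[m$best_epoch])
})

test_that("training and inference are seed-deterministic and inference is pure", {
  set.seed(6)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- sin(x[, 1]) + x[, 2]
  cfg <- fast_config("bilstm", seed = 13L)
  m1 <- train_model(build_model(cfg, 2L), x, y)
  m2 <- train_model(build_model(cfg, 2L), x, y)
  expect_identical(m1$history$val_mse, m2$history$val_mse)
  expect_identical(m1$weights, m2$weights)
  p1 <- predict(m1, x)
  expect_identical(p1, predict(m1, x))
  # constant-input batch -> constant output
  xc <- matrix(0.3, 7, 2)
  expect_equal(predict(m1, xc), rep(predict(m1, xc[1, , drop = FALSE]), 7))
  expect_error(predict(m1, matrix(0, 3, 5)), "features")
})

test_that("checkpoints round-trip through the text format", {
  set.seed(8)
  x <- matrix(rnorm(30 * 2), 30, 2)
  y <- x[, 1] - x[, 2]
  m <- train_model(build_model(fast_config("gru"), 2L), x, y)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  back <- load_model(dir)
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
  expect_equal(back$config$arch, "gru")
  expect_equal(nrow(back$history), nrow(m$history))
})

test_that("training loss trends downward on a noise-free deterministic mapping", {
  set.seed(10)
  x <- matrix(runif(200 * 2), 200, 2)
  y <- 2 * x[, 1] + 3 * x[, 2]
  cfg <- model_config("lstm", recurrent_units = 12L, dense_units = 12L,
                      dropout = 0, max_epochs = 40L, patience = 40L,
                      batch_size = 32L, seed = 3L)
  m <- train_model(build_model(cfg, 2L), x, y)
  tr <- m$history$train_mse
  half <- floor(length(tr) / 2)
  expect_lt(mean(tr[(half + 1):length(tr)]), mean(tr[seq_len(half)]))
  expect_lt(utils::tail(tr, 1), tr[1])
})

test_that("the reduced grid utility ranks candidates and refuses large grids", {
  set.seed(12)
  x <- matrix(rnorm(50 * 2), 50, 2)
  y <- x[, 1]
  res <- grid_search(list(fast_config("lstm"), fast_config("gru")), x, y)
  expect_equal(nrow(res), 2L)
  expect_true(!is.unsorted(res$val_mse))
  expect_error(grid_search(rep(list(fast_config()), 9L), x, y), "at most 8")
})
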