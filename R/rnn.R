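# Recurrent sequence regressors (LSTM, BiLSTM, GRU) implemented in base R
# matrix code: forward pass, full backpropagation through time, Adam, and
# early stopping with best-weight restoration. Layer stack: sequence input
# -> stacked recurrent layers -> dropout -> dense (ReLU) -> dropout ->
# linear scalar output (no activation on the regression head).

#' Model configuration
#'
#' Defaults are the desk-scale profile (32 recurrent units, 32 dense
#' units, batch 64) used throughout the tests; [fullscale_model_config()]
#' returns the full-scale profile (1024/1024).
#'
#' @param arch `"lstm"`, `"bilstm"` or `"gru"`.
#' @param recurrent_units hidden width of each recurrent layer.
#' @param n_recurrent_layers number of stacked recurrent layers.
#' @param dropout dropout fraction in \[0, 1).
#' @param dense_units width of the fully connected layer.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping (0 = stop at the first non-improvement).
#' @param val_fraction fraction of training rows held out for validation
#'   (chronologically last rows per subject).
#' @param seq_len timestamps per sample in the \[samples, timestamps,
#'   features\] input.
#' @param seed seed governing initialization, shuffling and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(arch = c("bilstm", "lstm", "gru"),
                         recurrent_units = 32L, n_recurrent_layers = 2L,
                         dropout = 0.3, dense_units = 32L,
                         learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 100L, patience = 10L,
                         val_fraction = 0.1, seq_len = 1L, seed = 1L) {
  arch <- match.arg(arch)
  check_scalar(dropout, "dropout", 0)
  if (dropout >= 1) stop_user("dropout must be < 1")
  check_scalar(seq_len, "seq_len", 1)
  check_scalar(max_epochs, "max_epochs", 1)
  check_scalar(recurrent_units, "recurrent_units", 1)
  check_scalar(val_fraction, "val_fraction", 0)
  structure(list(arch = arch, recurrent_units = as.integer(recurrent_units),
                 n_recurrent_layers = as.integer(n_recurrent_layers),
                 dropout = dropout, dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, seq_len = as.integer(seq_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Full-scale model profile
#'
#' @inheritParams model_config
#' @param ... overrides passed to [model_config()].
#' @return A `model_config` with 1024 recurrent and dense units.
#' @export
fullscale_model_config <- function(arch = "bilstm", ...) {
  model_config(arch = arch, recurrent_units = 1024L, dense_units = 1024L, ...)
}

n_gates <- function(arch) if (arch == "gru") 3L else 4L
is_bidir <- function(arch) arch == "bilstm"

glorot <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -s, s), nr, nc)
}

# Weight names: rnn<l>.<dir>.{W,U,b}, dense.{W,b}, out.{W,b}.
# Single-bias gate convention; LSTM gate order i,f,g,o (forget bias 1);
# GRU order r,z,n with reset applied before the candidate matmul
# (h' = (1-z)*n + z*h). Recorded here so parameter-count oracles are
# unambiguous.
init_weights <- function(config, n_features) {
  G <- n_gates(config$arch)
  h <- config$recurrent_units
  dirs <- if (is_bidir(config$arch)) c("fwd", "bwd") else "fwd"
  w <- list()
  d_in <- n_features
  for (l in seq_len(config$n_recurrent_layers)) {
    for (dir in dirs) {
      p <- paste0("rnn", l, ".", dir, ".")
      w[[paste0(p, "W")]] <- glorot(d_in, G * h)
      w[[paste0(p, "U")]] <- glorot(h, G * h)
      b <- rep(0, G * h)
      if (G == 4L) b[(h + 1L):(2L * h)] <- 1     # forget-gate bias
      w[[paste0(p, "b")]] <- b
    }
    d_in <- h * length(dirs)
  }
  w[["dense.W"]] <- glorot(d_in, config$dense_units)
  w[["dense.b"]] <- rep(0, config$dense_units)
  w[["out.W"]] <- glorot(config$dense_units, 1L)
  w[["out.b"]] <- 0
  w
}

#' Build an (untrained) sequence regressor
#'
#' @param config a [model_config()].
#' @param n_features number of input features per time step.
#' @return An object of class `vo2_model` with freshly initialized
#'   weights, empty history and a fixed input width.
#' @export
build_model <- function(config, n_features) {
  stopifnot(inherits(config, "model_config"))
  if (n_features < 1L) stop_user("n_features must be >= 1")
  weights <- with_seed(derive_seed(config$seed, "init"),
                       init_weights(config, as.integer(n_features)))
  structure(list(config = config, n_features = as.integer(n_features),
                 weights = weights, history = NULL, trained = FALSE),
            class = "vo2_model")
}

#' @export
print.vo2_model <- function(x, ...) {
  cat(sprintf("<vo2_model> %s | %d rec layers x %d units | dense %d | %d features | %s\n",
              toupper(x$config$arch), x$config$n_recurrent_layers,
              x$config$recurrent_units, x$config$dense_units, x$n_features,
              if (x$trained) sprintf("trained (%d epochs)", nrow(x$history))
              else "untrained"))
  cat("  parameters:", count_params(x), "\n")
  invisible(x)
}

#' Trainable parameter count
#'
#' A width-h unidirectional layer on d inputs has `4(dh + h^2 + h)`
#' weights for LSTM and `3(dh + h^2 + h)` for GRU (single-bias
#' convention); bidirectional layers double that.
#'
#' @param model a `vo2_model`.
#' @return total number of scalar parameters.
#' @export
count_params <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

sigm <- function(x) 1 / (1 + exp(-x))

# one recurrent layer over a list of T input matrices (B x d each);
# returns per-step outputs plus the cache needed for BPTT.
layer_forward <- function(Xs, W, U, b, arch, reverse = FALSE) {
  Tn <- length(Xs)
  B <- nrow(Xs[[1L]])
  h <- nrow(U)
  gru <- arch == "gru"
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  order <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  outs <- vector("list", Tn)
  cache <- vector("list", Tn)
  brow <- matrix(b, B, length(b), byrow = TRUE)
  for (t in order) {
    Xt <- Xs[[t]]
    Hprev <- H; Cprev <- C
    if (gru) {
      Ax <- Xt %*% W + brow
      Ah <- Hprev %*% U
      r <- sigm(Ax[, 1:h, drop = FALSE] + Ah[, 1:h, drop = FALSE])
      z <- sigm(Ax[, (h + 1):(2 * h), drop = FALSE] + Ah[, (h + 1):(2 * h), drop = FALSE])
      rh <- r * Hprev
      n <- tanh(Ax[, (2 * h + 1):(3 * h), drop = FALSE] +
                  rh %*% U[, (2 * h + 1):(3 * h), drop = FALSE])
      H <- (1 - z) * n + z * Hprev
      cache[[t]] <- list(Xt = Xt, Hprev = Hprev, r = r, z = z, n = n, rh = rh)
    } else {
      A <- Xt %*% W + Hprev %*% U + brow
      i <- sigm(A[, 1:h, drop = FALSE])
      f <- sigm(A[, (h + 1):(2 * h), drop = FALSE])
      g <- tanh(A[, (2 * h + 1):(3 * h), drop = FALSE])
      o <- sigm(A[, (3 * h + 1):(4 * h), drop = FALSE])
      C <- f * Cprev + i * g
      tc <- tanh(C)
      H <- o * tc
      cache[[t]] <- list(Xt = Xt, Hprev = Hprev, Cprev = Cprev,
                         i = i, f = f, g = g, o = o, tc = tc)
    }
    outs[[t]] <- H
  }
  list(outs = outs, cache = cache, order = order, final = H)
}

# BPTT through one layer. dOuts: list of per-step output gradients (NULL
# = zero); dFinal: extra gradient on the direction's final hidden state.
layer_backward <- function(dOuts, dFinal, fwd, W, U, arch) {
  Tn <- length(fwd$cache)
  B <- nrow(fwd$cache[[fwd$order[1L]]]$Xt)
  h <- nrow(U)
  gru <- arch == "gru"
  dW <- W * 0; dU <- U * 0; db <- numeric(ncol(U))
  dXs <- vector("list", Tn)
  dH <- matrix(0, B, h); dC <- matrix(0, B, h)
  for (t in rev(fwd$order)) {
    cc <- fwd$cache[[t]]
    dHt <- dH
    if (!is.null(dOuts[[t]])) dHt <- dHt + dOuts[[t]]
    if (t == fwd$order[Tn] && !is.null(dFinal)) dHt <- dHt + dFinal
    if (gru) {
      r <- cc$r; z <- cc$z; n <- cc$n
      dz <- dHt * (cc$Hprev - n)
      dn <- dHt * (1 - z)
      dHprev <- dHt * z
      dAn <- dn * (1 - n^2)
      Un <- U[, (2 * h + 1):(3 * h), drop = FALSE]
      drh <- dAn %*% t(Un)
      dr <- drh * cc$Hprev
      dHprev <- dHprev + drh * r
      dAr <- dr * r * (1 - r)
      dAz <- dz * z * (1 - z)
      dA <- cbind(dAr, dAz, dAn)
      dW <- dW + crossprod(cc$Xt, dA)
      dU[, 1:(2 * h)] <- dU[, 1:(2 * h), drop = FALSE] +
        crossprod(cc$Hprev, dA[, 1:(2 * h), drop = FALSE])
      dU[, (2 * h + 1):(3 * h)] <- dU[, (2 * h + 1):(3 * h), drop = FALSE] +
        crossprod(cc$rh, dAn)
      db <- db + colSums(dA)
      dXs[[t]] <- dA %*% t(W)
      dHprev <- dHprev + dA[, 1:(2 * h), drop = FALSE] %*%
        t(U[, 1:(2 * h), drop = FALSE])
      dH <- dHprev
    } else {
      i <- cc$i; f <- cc$f; g <- cc$g; o <- cc$o; tc <- cc$tc
      do_ <- dHt * tc
      dCt <- dC + dHt * o * (1 - tc^2)
      di <- dCt * g
      df <- dCt * cc$Cprev
      dg <- dCt * i
      dC <- dCt * f
      dA <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - g^2), do_ * o * (1 - o))
      dW <- dW + crossprod(cc$Xt, dA)
      dU <- dU + crossprod(cc$Hprev, dA)
      db <- db + colSums(dA)
      dXs[[t]] <- dA %*% t(W)
      dH <- dA %*% t(U)
    }
  }
  list(dW = dW, dU = dU, db = db, dXs = dXs)
}

# full network forward. X: [B, T, d] array. Returns prediction and, when
# train = TRUE, all caches (dropout masks drawn from the current RNG).
net_forward <- function(weights, config, X, train = FALSE) {
  B <- dim(X)[1L]; Tn <- dim(X)[2L]
  dirs <- if (is_bidir(config$arch)) c("fwd", "bwd") else "fwd"
  Xs <- lapply(seq_len(Tn), function(t) matrix(X[, t, ], nrow = B))
  layers <- vector("list", config$n_recurrent_layers)
  for (l in seq_len(config$n_recurrent_layers)) {
    runs <- lapply(dirs, function(dir) {
      p <- paste0("rnn", l, ".", dir, ".")
      layer_forward(Xs, weights[[paste0(p, "W")]], weights[[paste0(p, "U")]],
                    weights[[paste0(p, "b")]], config$arch,
                    reverse = dir == "bwd")
    })
    names(runs) <- dirs
    layers[[l]] <- runs
    Xs <- lapply(seq_len(Tn), function(t)
      do.call(cbind, lapply(runs, function(r) r$outs[[t]])))
  }
  # regression head reads each direction's final hidden state
  Hlast <- do.call(cbind, lapply(layers[[config$n_recurrent_layers]],
                                 function(r) r$final))
  p <- config$dropout
  if (train && p > 0) {
    m1 <- matrix(stats::rbinom(length(Hlast), 1L, 1 - p), nrow(Hlast)) / (1 - p)
    Hd <- Hlast * m1
  } else { m1 <- NULL; Hd <- Hlast }
  Z <- Hd %*% weights[["dense.W"]] +
    matrix(weights[["dense.b"]], B, config$dense_units, byrow = TRUE)
  A <- pmax(Z, 0)
  if (train && p > 0) {
    m2 <- matrix(stats::rbinom(length(A), 1L, 1 - p), nrow(A)) / (1 - p)
    Ad <- A * m2
  } else { m2 <- NULL; Ad <- A }
  yhat <- drop(Ad %*% weights[["out.W"]] + weights[["out.b"]])
  list(yhat = yhat, layers = layers, Hlast = Hlast, Hd = Hd, Z = Z,
       A = A, Ad = Ad, m1 = m1, m2 = m2, Tn = Tn, B = B)
}

# gradients of mean squared error wrt all weights
net_backward <- function(weights, config, X, y, fw) {
  B <- fw$B; Tn <- fw$Tn
  dirs <- if (is_bidir(config$arch)) c("fwd", "bwd") else "fwd"
  h <- config$recurrent_units
  g <- list()
  dyhat <- matrix(2 * (fw$yhat - y) / B, ncol = 1L)
  g[["out.W"]] <- crossprod(fw$Ad, dyhat)
  g[["out.b"]] <- sum(dyhat)
  dAd <- dyhat %*% t(weights[["out.W"]])
  dA <- if (is.null(fw$m2)) dAd else dAd * fw$m2
  dZ <- dA * (fw$Z > 0)
  g[["dense.W"]] <- crossprod(fw$Hd, dZ)
  g[["dense.b"]] <- colSums(dZ)
  dHd <- dZ %*% t(weights[["dense.W"]])
  dHlast <- if (is.null(fw$m1)) dHd else dHd * fw$m1
  # split the head gradient across the top layer's direction finals
  dFinal <- list()
  for (k in seq_along(dirs))
    dFinal[[dirs[k]]] <- dHlast[, ((k - 1) * h + 1):(k * h), drop = FALSE]
  dOuts <- replicate(length(dirs), vector("list", Tn), simplify = FALSE)
  names(dOuts) <- dirs
  for (l in rev(seq_len(config$n_recurrent_layers))) {
    runs <- fw$layers[[l]]
    dX_accum <- NULL
    for (k in seq_along(dirs)) {
      dir <- dirs[k]
      p <- paste0("rnn", l, ".", dir, ".")
      bk <- layer_backward(dOuts[[dir]],
                           if (l == config$n_recurrent_layers) dFinal[[dir]] else NULL,
                           runs[[dir]], weights[[paste0(p, "W")]],
                           weights[[paste0(p, "U")]], config$arch)
      g[[paste0(p, "W")]] <- bk$dW
      g[[paste0(p, "U")]] <- bk$dU
      g[[paste0(p, "b")]] <- bk$db
      if (is.null(dX_accum)) dX_accum <- bk$dXs
      else dX_accum <- lapply(seq_len(Tn), function(t) dX_accum[[t]] + bk$dXs[[t]])
    }
    if (l > 1L) {
      # route dX into the lower layer's per-direction, per-step outputs
      for (k in seq_along(dirs)) {
        cols <- ((k - 1) * h + 1):(k * h)
        dOuts[[dirs[k]]] <- lapply(dX_accum, function(m) m[, cols, drop = FALSE])
      }
      dFinal <- stats::setNames(vector("list", length(dirs)), dirs)  # only head hits finals
    }
  }
  g
}

mse_of <- function(y, yhat) mean((y - yhat)^2)

#' Reshape a feature table into \[samples, timestamps, features\]
#'
#' Assigns non-overlapping runs of `seq_len` consecutive rows to one
#' sample each (per subject; a sample never spans subjects); the sample's
#' target is the last row's VO2. Leftover rows that do not fill a window
#' are dropped.
#'
#' @param table a feature table ordered in time within subject.
#' @param seq_len timestamps per sample.
#' @param cols feature columns to use (default: all).
#' @return list with `X` (\[n, seq_len, d\] array), `y`, `subjects`
#'   (per-sample subject id) and, when present, `y_truth`.
#' @export
reshape_for_sequence <- function(table, seq_len = 1L,
                                 cols = feature_columns(table)) {
  seq_len <- as.integer(seq_len)
  ids <- unique(table$subject_id)
  Xb <- list(); yb <- list(); sb <- list(); tb <- list()
  has_truth <- "target_truth" %in% names(table)
  for (id in ids) {
    rows <- which(table$subject_id == id)
    if (seq_len > length(rows))
      stop_user("seq_len exceeds rows for subject ", id)
    nwin <- length(rows) %/% seq_len
    take <- rows[seq_len(nwin * seq_len)]
    m <- as.matrix(table[take, cols, with = FALSE])
    a <- array(0, c(nwin, seq_len, ncol(m)))
    for (t in seq_len(seq_len))
      a[, t, ] <- m[seq(t, by = seq_len, length.out = nwin), , drop = FALSE]
    last <- take[seq(seq_len, by = seq_len, length.out = nwin)]
    Xb[[id]] <- a
    yb[[id]] <- table$target[last]
    if (has_truth) tb[[id]] <- table$target_truth[last]
    sb[[id]] <- rep(id, nwin)
  }
  n <- sum(vapply(Xb, function(a) dim(a)[1L], integer(1)))
  d <- length(cols)
  X <- array(0, c(n, seq_len, d))
  at <- 0L
  for (id in ids) {
    ni <- dim(Xb[[id]])[1L]
    X[at + seq_len(ni), , ] <- Xb[[id]]
    at <- at + ni
  }
  out <- list(X = X, y = unlist(yb, use.names = FALSE),
              subjects = unlist(sb, use.names = FALSE), cols = cols)
  if (has_truth) out$y_truth <- unlist(tb, use.names = FALSE)
  out
}

#' Train a sequence regressor
#'
#' Adam on the mean-squared-error loss, minibatched with a seeded shuffle
#' per epoch, dropout active, validation on the chronologically last
#' `val_fraction` of each subject's samples, early stopping after
#' `patience` consecutive epochs without validation improvement, and
#' restoration of the best-validation weights. A fixed seed (and
#' single-threaded BLAS) makes the returned weights reproducible.
#'
#' @param model an untrained (or trained) `vo2_model` from [build_model()].
#' @param X input array \[samples, timestamps, features\] (a plain matrix
#'   is accepted when `seq_len` is 1).
#' @param y numeric target vector (mL/kg/min).
#' @param subjects optional per-sample subject ids for the chronological
#'   validation split; without them the split is the last fraction of all
#'   samples.
#' @return the trained `vo2_model` with `history` (epoch, train_mse,
#'   val_mse) and best weights restored.
#' @export
train_model <- function(model, X, y, subjects = NULL) {
  stopifnot(inherits(model, "vo2_model"))
  config <- model$config
  if (is.matrix(X)) X <- array(X, c(nrow(X), 1L, ncol(X)))
  if (dim(X)[3L] != model$n_features)
    stop_user("X has ", dim(X)[3L], " features; model expects ", model$n_features)
  n <- dim(X)[1L]
  if (length(y) != n) stop_user("X and y lengths differ")
  if (config$val_fraction <= 0) stop_user("val_fraction must be > 0 for early stopping")
  # chronological validation split (last fraction per subject)
  val_idx <- if (is.null(subjects)) {
    seq.int(max(1L, floor(n * (1 - config$val_fraction)) + 1L), n)
  } else {
    unlist(lapply(unique(subjects), function(id) {
      w <- which(subjects == id)
      nv <- max(1L, floor(length(w) * config$val_fraction))
      w[(length(w) - nv + 1L):length(w)]
    }), use.names = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (!length(tr_idx)) stop_user("no training samples left after validation split")
  Xtr <- X[tr_idx, , , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , , drop = FALSE]; yva <- y[val_idx]
  w <- model$weights
  mom <- lapply(w, function(m) m * 0)
  vel <- lapply(w, function(m) m * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsadam <- 1e-8
  lr <- config$learning_rate
  step <- 0L
  best_val <- Inf; best_w <- w; best_epoch <- 0L; bad <- 0L
  hist <- list()
  with_seed(derive_seed(config$seed, "train"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(length(tr_idx))
      ep_loss <- 0; ep_n <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        Xb <- Xtr[bi, , , drop = FALSE]; yb <- ytr[bi]
        fw <- net_forward(w, config, Xb, train = TRUE)
        loss <- mse_of(yb, fw$yhat)
        if (!is.finite(loss))
          stop_user("NaN/Inf training loss at epoch ", epoch,
                    "; reduce the learning rate or rescale inputs")
        gr <- net_backward(w, config, Xb, yb, fw)
        step <- step + 1L
        bc <- lr * sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(w)) {
          mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * gr[[nm]]
          vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * gr[[nm]]^2
          w[[nm]] <- w[[nm]] - bc * mom[[nm]] / (sqrt(vel[[nm]]) + epsadam)
        }
        ep_loss <- ep_loss + loss * length(bi); ep_n <- ep_n + length(bi)
      }
      val_mse <- mse_of(yva, net_forward(w, config, Xva, train = FALSE)$yhat)
      hist[[epoch]] <- data.frame(epoch = epoch, train_mse = ep_loss / ep_n,
                                  val_mse = val_mse)
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse; best_w <- w; best_epoch <- epoch; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad > config$patience) break
      }
    }
  })
  model$weights <- best_w
  model$history <- do.call(rbind, hist)
  model$best_epoch <- best_epoch
  model$trained <- TRUE
  model
}

#' Predict VO2 for new samples
#'
#' Deterministic inference (dropout disabled); one scalar per sample.
#'
#' @param object a trained `vo2_model`.
#' @param X input array \[samples, timestamps, features\] or matrix when
#'   `seq_len` is 1.
#' @param ... unused.
#' @return numeric vector of VO2 estimates, mL/kg/min.
#' @export
predict.vo2_model <- function(object, X, ...) {
  if (is.matrix(X)) X <- array(X, c(nrow(X), 1L, ncol(X)))
  if (dim(X)[3L] != object$n_features)
    stop_user("X has ", dim(X)[3L], " features; model expects ",
              object$n_features)
  net_forward(object$weights, object$config, X, train = FALSE)$yhat
}

#' Save / load a model checkpoint directory
#'
#' Writes `config.txt` (key-value), `weights.csv` (name, row, col, value)
#' and `history.csv` so a run directory is fully text-based.
#'
#' @param model a `vo2_model`.
#' @param dir checkpoint directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- model$config
  write_keyvalue(c(cfg, list(n_features = model$n_features,
                             trained = as.integer(model$trained))),
                 file.path(dir, "config.txt"))
  wl <- lapply(names(model$weights), function(nm) {
    m <- model$weights[[nm]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    data.table::data.table(name = nm,
                           row = rep(seq_len(nrow(m)), ncol(m)),
                           col = rep(seq_len(ncol(m)), each = nrow(m)),
                           value = as.vector(m))
  })
  data.table::fwrite(data.table::rbindlist(wl), file.path(dir, "weights.csv"))
  if (!is.null(model$history))
    data.table::fwrite(model$history, file.path(dir, "history.csv"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  kv <- read_keyvalue(file.path(dir, "config.txt"))
  config <- model_config(arch = kv_chr(kv, "arch"),
                         recurrent_units = kv_num(kv, "recurrent_units"),
                         n_recurrent_layers = kv_num(kv, "n_recurrent_layers"),
                         dropout = kv_num(kv, "dropout"),
                         dense_units = kv_num(kv, "dense_units"),
                         learning_rate = kv_num(kv, "learning_rate"),
                         batch_size = kv_num(kv, "batch_size"),
                         max_epochs = kv_num(kv, "max_epochs"),
                         patience = kv_num(kv, "patience"),
                         val_fraction = kv_num(kv, "val_fraction"),
                         seq_len = kv_num(kv, "seq_len"),
                         seed = kv_num(kv, "seed"))
  model <- build_model(config, kv_num(kv, "n_features"))
  wdt <- data.table::fread(file.path(dir, "weights.csv"))
  for (nm in names(model$weights)) {
    sub <- wdt[wdt$name == nm]
    tmpl <- model$weights[[nm]]
    if (is.null(dim(tmpl))) {
      v <- numeric(length(tmpl)); v[sub$row] <- sub$value
      model$weights[[nm]] <- v
    } else {
      m <- tmpl * 0; m[cbind(sub$row, sub$col)] <- sub$value
      model$weights[[nm]] <- m
    }
  }
  hpath <- file.path(dir, "history.csv")
  if (file.exists(hpath)) model$history <- as.data.frame(data.table::fread(hpath))
  model$trained <- as.logical(kv_num(kv, "trained", 0))
  model
}

#' Reduced-grid hyperparameter search
#'
#' Trains at most eight candidate configurations on a fixed split and
#' ranks them by final validation MSE. A deliberately small utility: the
#' full-scale random-search tuning of the original protocol is out of
#' scope.
#'
#' @param configs list of [model_config()] (length <= 8).
#' @param X,y,subjects training inputs as for [train_model()].
#' @return data.frame of candidates ranked by validation MSE, with the
#'   fitted models attached as attribute `models`.
#' @export
grid_search <- function(configs, X, y, subjects = NULL) {
  if (length(configs) > 8L)
    stop_user("grid_search is a reduced utility: at most 8 configurations")
  fits <- lapply(configs, function(cfg) {
    d <- if (is.matrix(X)) ncol(X) else dim(X)[3L]
    train_model(build_model(cfg, d), X, y, subjects)
  })
  res <- data.frame(
    candidate = seq_along(configs),
    arch = vapply(configs, `[[`, character(1), "arch"),
    recurrent_units = vapply(configs, `[[`, numeric(1), "recurrent_units"),
    val_mse = vapply(fits, function(m) min(m$history$val_mse), numeric(1))
  )
  res <- res[order(res$val_mse), ]
  attr(res, "models") <- fits
  res
}
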