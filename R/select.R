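# Feature selection (Pearson + kNN mutual information) and min-max scaling.

#' Mutual information between two continuous variables
#'
#' Kraskov k-nearest-neighbour (KSG) estimator in nats. Both marginals are
#' standardized and a deterministic, seeded jitter (1e-10 of one standard
#' deviation) breaks ties so the estimate is reproducible on quantized
#' inputs. Rows beyond `max_n` are reduced by an evenly strided,
#' deterministic subsample; this is an estimator setting, not randomness.
#'
#' @param x,y numeric vectors of equal length.
#' @param k neighbour count (default 3).
#' @param max_n subsample cap for the O(n^2) neighbour search.
#' @param jitter_seed seed of the tie-breaking jitter.
#' @return estimated mutual information, nats (>= 0).
#' @export
mutual_information <- function(x, y, k = 3L, max_n = 2000L, jitter_seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop_user("x and y lengths differ")
  if (n <= k + 1L) stop_user("fewer rows than the MI neighbour count")
  if (n > max_n) {
    idx <- unique(round(seq(1L, n, length.out = max_n)))
    x <- x[idx]; y <- y[idx]; n <- length(idx)
  }
  zx <- sd(x); zy <- sd(y)
  if (zx == 0 || zy == 0) return(0)
  x <- (x - mean(x)) / zx
  y <- (y - mean(y)) / zy
  jit <- with_seed(jitter_seed, matrix(runif(2L * n, -1, 1), n, 2L)) * 1e-10
  ksg_mi(x + jit[, 1L], y + jit[, 2L], as.integer(k))
}

#' Select features by Pearson correlation and mutual information
#'
#' A feature is kept iff both its absolute Pearson correlation with the
#' target and its KSG mutual information with the target exceed their
#' thresholds (both 0.1 by default). Zero-variance features get r = 0 and
#' MI = 0 and are never kept. Deterministic given the estimator settings.
#'
#' @param table a feature table from [build_feature_table()].
#' @param r_threshold absolute-correlation threshold.
#' @param mi_threshold mutual-information threshold, nats.
#' @param candidate_cols features to score (default: all feature columns).
#' @param k,max_n,jitter_seed passed to [mutual_information()].
#' @return An object of class `selection_result`: data.frame with columns
#'   `feature`, `pearson_r`, `mutual_info`, `kept`, plus threshold
#'   attributes.
#' @export
select_features <- function(table, r_threshold = 0.1, mi_threshold = 0.1,
                            candidate_cols = feature_columns(table),
                            k = 3L, max_n = 2000L, jitter_seed = 1L) {
  if (nrow(table) < 10L) stop_user("need at least 10 rows to select features")
  y <- table$target
  if (sd(y) == 0) stop_user("target has zero variance")
  r <- vapply(candidate_cols, function(cn) {
    x <- table[[cn]]
    if (sd(x) == 0) return(0)
    cor(x, y)
  }, numeric(1))
  mi <- vapply(candidate_cols, function(cn) {
    mutual_information(table[[cn]], y, k = k, max_n = max_n,
                       jitter_seed = jitter_seed)
  }, numeric(1))
  res <- data.frame(feature = candidate_cols, pearson_r = unname(r),
                    mutual_info = unname(mi),
                    kept = abs(unname(r)) > r_threshold & unname(mi) > mi_threshold,
                    row.names = NULL)
  structure(res, class = c("selection_result", "data.frame"),
            r_threshold = r_threshold, mi_threshold = mi_threshold)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", sum(x$kept), "of", nrow(x), "features kept",
      sprintf("(|r| > %g and MI > %g nats)\n",
              attr(x, "r_threshold"), attr(x, "mi_threshold")))
  invisible(x)
}

#' Kept feature names of a selection result
#'
#' @param selection a `selection_result`.
#' @return character vector of kept feature names.
#' @export
kept_features <- function(selection) selection$feature[selection$kept]

#' Write / read a selection report
#'
#' @param selection a `selection_result`.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_selection <- function(selection, path) {
  data.table::fwrite(data.table::as.data.table(selection), path)
  invisible(path)
}

#' Fit a min-max scaler on a row subset
#'
#' Records per-feature min and max over the fitting rows. Applying the
#' scaler maps x to (x - min) / (max - min); constant columns map to 0;
#' values outside the fitted range (as happens on held-out folds) are not
#' clipped.
#'
#' @param table a feature table.
#' @param rows_mask logical/integer row subset to fit on (default: all).
#' @param cols feature columns to scale (default: all feature columns).
#' @return An object of class `scaler_state`.
#' @export
fit_scaler <- function(table, rows_mask = NULL, cols = feature_columns(table)) {
  sub <- if (is.null(rows_mask)) table else table[rows_mask, , drop = FALSE]
  if (nrow(sub) < 1L) stop_user("scaler fitting partition is empty")
  mins <- vapply(cols, function(cn) min(sub[[cn]]), numeric(1))
  maxs <- vapply(cols, function(cn) max(sub[[cn]]), numeric(1))
  structure(list(cols = cols, min = mins, max = maxs), class = "scaler_state")
}

#' Apply a fitted min-max scaler
#'
#' @param state a `scaler_state` from [fit_scaler()].
#' @param table a feature table containing the scaler's columns.
#' @return the table with scaled feature columns (metadata untouched).
#' @export
apply_scaler <- function(state, table) {
  stopifnot(inherits(state, "scaler_state"))
  out <- data.table::as.data.table(table)
  for (cn in state$cols) {
    rng <- state$max[[cn]] - state$min[[cn]]
    v <- if (rng == 0) rep(0, nrow(out)) else (out[[cn]] - state$min[[cn]]) / rng
    data.table::set(out, j = cn, value = v)
  }
  out[]
}
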