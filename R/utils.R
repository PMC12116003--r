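# Internal helpers: seed derivation, validation, key-value config files.

#' @useDynLib wearvo2, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats cor quantile rnorm runif sd var median pf pt qt setNames predict
#' @importFrom utils modifyList
NULL

# Derive a reproducible child seed from a master seed and a stream label.
# Keeps everything below 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647L)
}

# Run an expression with a local RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("wearvo2_user_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_user(name, " must be a single number")
  if (strict_lower && x <= lower) stop_user(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop_user(name, " must be >= ", lower)
  if (x > upper) stop_user(name, " must be <= ", upper)
  invisible(x)
}

# Key-value text files: "key = value" lines, "#" comments, optional [sections]
# flattened as section.key. Used for cohort manifests, run configs, summaries.
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop_user("malformed key-value line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(section)) key <- paste0(section, ".", key)
    out[[key]] <- val
  }
  out
}

write_keyvalue <- function(x, path) {
  lines <- vapply(names(x), function(k) {
    paste0(k, " = ", paste(x[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

kv_num <- function(kv, key, default = NULL) {
  if (is.null(kv[[key]])) return(default)
  as.numeric(kv[[key]])
}

kv_chr <- function(kv, key, default = NULL) {
  if (is.null(kv[[key]])) return(default)
  kv[[key]]
}
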