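# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered-pair key; lexicographic so it is invariant to the
# order genes arrive in.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

split_edge_key <- function(key) {
  do.call(rbind, strsplit(key, "|", fixed = TRUE))
}

assert_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

assert_matrix <- function(x, name) {
  if (!is.matrix(x) && !is.data.frame(x)) {
    stop(sprintf("`%s` must be a matrix or data frame", name), call. = FALSE)
  }
  as.matrix(x)
}

# Column-wise standard deviations without apply() overhead.
col_sds <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  sqrt((colSums(x^2) - n * mu^2) / (n - 1))
}

# Build a numeric design matrix (no intercept column) from a data frame of
# covariates; factors/characters are expanded to dummies.
design_from_df <- function(df) {
  if (is.null(df) || NCOL(df) == 0) return(NULL)
  if (is.matrix(df)) return(df)
  df <- as.data.frame(df)
  mm <- stats::model.matrix(~., data = df)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

# Small rolling polynomial hash of a serialized object; used to stamp
# output tables so a table can be traced back to the configuration that
# produced it.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Draw a fresh stream of sub-seeds from one root seed so that stages are
# individually reproducible.
derive_seeds <- function(seed, n, labels = NULL) {
  stopifnot(length(seed) == 1, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(labels)) names(s) <- labels
  s
}
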