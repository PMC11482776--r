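# Internal helpers shared across modules.

# Deterministically derive a child seed from a run seed and a sequence of
# string/integer tags. Every source of randomness in the package draws its
# seed through this, so one run seed reproduces the whole analysis while
# keeping folds, permutations and ensemble members independent.
derive_seed <- function(seed, ...) {
  tags <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (tag in tags) {
    for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645 + 1)
}

# z-score a vector; constant vectors map to all zeros (their kernel matrix
# is constant either way, so downstream utilities are unaffected).
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

stop_hifit <- function(msg, class = "hifit_error") {
  abort(msg, class = class)
}

is_binary_vector <- function(y) {
  u <- unique(y[!is.na(y)])
  length(u) <= 2 && all(u %in% c(0, 1))
}

# Resolve the outcome type, inferring from the data when not given.
resolve_outcome_type <- function(y, outcome_type = NULL) {
  if (!is.null(outcome_type)) {
    return(match.arg(outcome_type, c("continuous", "binary")))
  }
  if (is_binary_vector(y)) "binary" else "continuous"
}

# Split a data frame with an outcome column into a numeric feature matrix
# and outcome vector. Non-numeric columns (sample identifiers and the like)
# are set aside, not screened.
prep_data <- function(data, outcome) {
  data <- as.data.frame(data)
  if (!outcome %in% names(data)) {
    stop_hifit(sprintf(
      "outcome column '%s' not found; available columns: %s",
      outcome, paste(names(data), collapse = ", ")
    ))
  }
  y <- data[[outcome]]
  if (!is.numeric(y)) stop_hifit("outcome column must be numeric")
  rest <- data[setdiff(names(data), outcome)]
  numeric_cols <- vapply(rest, is.numeric, logical(1))
  X <- as.matrix(rest[numeric_cols])
  if (anyNA(X) || anyNA(y)) stop_hifit("missing values are not supported")
  list(X = X, y = y, dropped = names(rest)[!numeric_cols])
}

# Deterministic, row-order-invariant fold assignment used for glmnet CV:
# rows are put in a canonical order (outcome, then features) and folds are
# dealt round-robin, so shuffling the input rows cannot change the fit.
canonical_foldid <- function(X, y, nfolds) {
  ord <- do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
  foldid <- integer(length(y))
  foldid[ord] <- rep_len(seq_len(nfolds), length(y))
  foldid
}
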