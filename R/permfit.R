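loss_vec <- function(y, pred, binary) {
  if (!binary) return((y - pred)^2)
  p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Permute one column of a feature table
#'
#' Replaces column `j` with a uniform random permutation of itself, leaving
#' every other column untouched (so the column's marginal distribution is
#' preserved while its link to the rows is broken).
#'
#' @param X Matrix or data frame.
#' @param j Column index or name.
#' @param seed Integer seed.
#' @return An object of the same shape as `X`.
#' @export
permute_column <- function(X, j, seed = 1) {
  n <- nrow(X)
  perm <- withr::with_seed(seed, sample.int(n))
  X[, j] <- X[perm, j]
  X
}

# Per-sample permutation-importance scores of one feature set.
#
# For each of n_perm permutations the columns in `idx_set` are permuted
# (each by its own permutation), predictions are recomputed, and the
# per-sample score is the increase in loss over the unpermuted prediction,
# averaged over permutations:
#   Lambda_hat_ij = mean_b loss(y_i, f(x_i, set permuted)) - loss(y_i, f(x_i)).
# All permuted copies are stacked into one predict call per set.
persample_scores <- function(model, Xv, yv, idx_set, n_perm, seed, binary) {
  nv <- nrow(Xv)
  if (nv < 2) stop_hifit("validation set must have at least 2 samples")
  l0 <- loss_vec(yv, predict(model, Xv), binary)
  Xbig <- Xv[rep(seq_len(nv), n_perm), , drop = FALSE]
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      rows <- (b - 1L) * nv + seq_len(nv)
      for (j in idx_set) Xbig[rows, j] <- Xv[sample.int(nv), j]
    }
  })
  lp <- matrix(loss_vec(rep(yv, n_perm), predict(model, Xbig), binary),
               nrow = nv)
  rowMeans(lp) - l0
}

# Mean / (population) SD / z / one-sided p of pooled per-sample scores.
summarize_scores <- function(scores) {
  nv <- length(scores)
  lambda <- mean(scores)
  sigma <- sqrt(mean((scores - lambda)^2))
  se <- sigma / sqrt(nv)
  if (se < .Machine$double.eps) {
    # a feature the model provably ignores: no evidence of importance
    z <- if (lambda > 0) Inf else NA_real_
    p <- if (lambda > 0) 0 else 1
  } else {
    z <- lambda / se
    p <- 1 - pnorm(z)
  }
  list(lambda_hat = lambda, se = se, z = z, p = p, n_val = nv)
}

#' Permutation importance of a single feature
#'
#' Estimates the importance score \eqn{\hat\Lambda_j}: the mean per-sample
#' increase in validation loss (squared error for continuous outcomes,
#' negative Bernoulli log-likelihood for binary ones) when feature `j` is
#' permuted, averaged over `n_perm` permutations. The one-sided z-test
#' \eqn{z = \hat\Lambda_j / (\hat\sigma_j / \sqrt{n_V})} is standard normal
#' under the null of no importance. The model must have been fitted on data
#' disjoint from `(data, outcome)`.
#'
#' @param model A fitted `hifit_model`.
#' @param data Validation data frame containing the model's feature columns
#'   and the outcome column.
#' @param outcome Outcome column name.
#' @param feature Feature name (or index into the model's feature list).
#' @param n_perm Number of permutations averaged over (default 100).
#' @param seed Integer seed.
#' @return A one-row tibble: `feature`, `lambda_hat`, `se`, `z`, `p`,
#'   `n_perm`, `n_val`.
#' @export
feature_importance <- function(model, data, outcome = "y", feature,
                               n_perm = 100, seed = 1) {
  ctx <- importance_context(model, data, outcome)
  j <- match_feature(model, feature)
  sc <- persample_scores(model, ctx$Xv, ctx$yv, j, n_perm, seed, ctx$binary)
  s <- summarize_scores(sc)
  tibble(feature = model$features[j], lambda_hat = s$lambda_hat, se = s$se,
         z = s$z, p = s$p, n_perm = n_perm, n_val = s$n_val)
}

#' Permutation importance of a feature set
#'
#' As [feature_importance()], but all features in the set are permuted
#' jointly (each column by its own permutation), giving one pooled
#' importance score for the whole set. With a single-feature set and the
#' same seed this reduces exactly to [feature_importance()].
#'
#' @inheritParams feature_importance
#' @param features Character vector of feature names (or indices) forming
#'   the set; non-empty subset of the model's features.
#' @return A one-row tibble with a `members` list-column and the same
#'   statistics as [feature_importance()].
#' @export
set_importance <- function(model, data, outcome = "y", features,
                           n_perm = 100, seed = 1) {
  if (length(features) == 0) stop_hifit("feature set must be non-empty")
  ctx <- importance_context(model, data, outcome)
  idx <- vapply(features, function(f) match_feature(model, f), integer(1))
  sc <- persample_scores(model, ctx$Xv, ctx$yv, idx, n_perm, seed, ctx$binary)
  s <- summarize_scores(sc)
  tibble(members = list(model$features[idx]), lambda_hat = s$lambda_hat,
         se = s$se, z = s$z, p = s$p, n_perm = n_perm, n_val = s$n_val)
}

#' Permutation importance test for every model feature
#'
#' Runs [feature_importance()] for each feature of the fitted model on
#' held-out validation data and returns the full importance table. P-values
#' are reported raw (the workflow's default significance cutoff is 0.1); a
#' Benjamini-Hochberg adjusted column is added when `adjust = TRUE`.
#'
#' @inheritParams feature_importance
#' @param features Features to test (default: all model features).
#' @param adjust Add a `p_adj` column with Benjamini-Hochberg adjusted
#'   p-values.
#' @return A tibble with one row per tested feature.
#' @export
#' @examples
#' sim <- simulate_dataset(n = 200, p = 12, seed = 1)
#' sp <- split_train_test(sim, seed = 2)
#' fit <- fit_learner(sp$train, "y", kind = "svm")
#' permfit(fit, sp$test, "y", n_perm = 20, seed = 3)
permfit <- function(model, data, outcome = "y", features = NULL,
                    n_perm = 100, seed = 1, adjust = FALSE) {
  features <- features %||% model$features
  out <- dplyr::bind_rows(lapply(features, function(f) {
    feature_importance(model, data, outcome, f, n_perm = n_perm,
                       seed = derive_seed(seed, "permfit", f))
  }))
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

importance_context <- function(model, data, outcome) {
  if (inherits(data, "hifit_sim")) data <- data$data
  prep <- prep_data(as.data.frame(data), outcome)
  missing <- setdiff(model$features, colnames(prep$X))
  if (length(missing)) {
    stop_hifit(paste("validation data lacks feature columns:",
                     paste(missing, collapse = ", ")))
  }
  list(Xv = prep$X[, model$features, drop = FALSE], yv = prep$y,
       binary = model$spec$outcome_type == "binary")
}

match_feature <- function(model, feature) {
  if (is.numeric(feature)) {
    j <- as.integer(feature)
    if (j < 1 || j > length(model$features)) stop_hifit("feature index out of range")
    return(j)
  }
  j <- match(feature, model$features)
  if (is.na(j)) stop_hifit(sprintf("feature '%s' is not in the model", feature))
  j
}
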