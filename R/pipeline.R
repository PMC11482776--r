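spec_with_seed <- function(spec, seed) {
  spec$seed <- seed
  spec
}

# Working models inside the cross-validation (cutoff tuning, importance
# estimation) skip hyperparameter tuning unless the caller asked for it
# explicitly: they only rank feature sets and score importances, and tuning
# them would nest a third cross-validation layer. The final reported model
# is fitted with the learner's full defaults (tuning included).
working_spec <- function(spec) {
  hp <- spec$hyperparameters
  if (spec$kind %in% c("svm", "xgb") && is.null(hp$tune)) {
    hp$tune <- FALSE
    spec$hyperparameters <- hp
  }
  spec
}

# Stratified (for binary outcomes) fold assignment, seeded.
make_folds <- function(y, K, seed, binary) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    if (binary) {
      if (min(table(y)) < K) {
        stop_hifit("too few samples of one class to stratify into K folds")
      }
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
      }
    } else {
      fold <- sample(rep_len(seq_len(K), length(y)))
    }
    fold
  })
}

split_half <- function(idx, y, seed, binary) {
  withr::with_seed(seed, {
    first <- if (binary) {
      unlist(lapply(split(idx, y[idx]), function(i) {
        sample(i, floor(length(i) / 2))
      }), use.names = FALSE)
    } else {
      sample(idx, floor(length(idx) / 2))
    }
    list(sort(first), sort(setdiff(idx, first)))
  })
}

# Combine the per-sample importance scores a feature collected over the 2K
# validation halves into one pooled test: the scores are concatenated and
# the usual importance z-statistic (mean over the pooled standard error of
# the mean) is formed. A feature that never passed screening carries
# importance 0 with p = 1.
summarize_half_scores <- function(half_scores, feature) {
  if (is.null(half_scores)) {
    return(tibble(feature = feature, lambda_hat = 0, se = 0,
                  z = NA_real_, p = 1, n_val = 0L, n_halves = 0L))
  }
  s <- summarize_scores(unlist(half_scores, use.names = FALSE))
  tibble(feature = feature, lambda_hat = s$lambda_hat, se = s$se,
         z = s$z, p = s$p, n_val = as.integer(s$n_val),
         n_halves = as.integer(length(half_scores)))
}

adaptive_cutoff_matrix <- function(anomaly, X_tr, y_tr, X_tu, y_tu, spec,
                                   candidates, n_perm, seed,
                                   keep_idx = integer(0)) {
  if (length(candidates) < 2 || is.unsorted(candidates, strictly = TRUE)) {
    stop_hifit("candidates must be at least two strictly increasing values")
  }
  tauR <- candidates[length(candidates)]
  S <- sort(union(which(!is.na(anomaly) & anomaly >= candidates[1]), keep_idx))
  if (length(S) == 0) {
    stop_hifit("no feature reaches the smallest candidate cutoff; lower tau0")
  }
  model <- fit_learner_matrix(
    working_spec(spec_with_seed(spec, derive_seed(seed, "cutfit"))),
    X_tr[, S, drop = FALSE], y_tr
  )
  binary <- spec$outcome_type == "binary"
  Xtu <- X_tu[, S, drop = FALSE]
  R <- length(candidates) - 1
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    members <- which(!is.na(anomaly) &
                       anomaly >= candidates[r] & anomaly < candidates[r + 1])
    if (length(members) == 0) {
      rows[[r]] <- tibble(lower = candidates[r], upper = candidates[r + 1],
                          n_features = 0L, lambda_hat = NA_real_, p = NA_real_)
      next
    }
    sc <- persample_scores(model, Xtu, y_tu, match(members, S), n_perm,
                           derive_seed(seed, "bin", r), binary)
    s <- summarize_scores(sc)
    rows[[r]] <- tibble(lower = candidates[r], upper = candidates[r + 1],
                        n_features = length(members),
                        lambda_hat = s$lambda_hat, p = s$p)
  }
  bins <- dplyr::bind_rows(rows)
  list(tau = choose_tau(bins$p, candidates), bins = bins, model = model, S = S)
}

# Decision rule: the chosen cutoff is the LOWER edge of the lowest-scoring
# bin with set importance p < 0.1, so every higher-scoring bin is retained
# as well; with no significant bin only the top candidates survive.
choose_tau <- function(bin_p, candidates) {
  sig <- which(!is.na(bin_p) & bin_p < 0.1)
  if (length(sig)) candidates[min(sig)] else candidates[length(candidates)]
}

#' Data-driven choice of the screening cutoff
#'
#' Bins the screened features by consecutive candidate cutoffs, fits the
#' learner on every feature above the smallest candidate, and estimates each
#' bin's joint permutation importance on a tuning set. The chosen cutoff is
#' the lower edge of the lowest-scoring bin whose set importance is
#' significant (p < 0.1), so all higher-scoring bins are retained as well;
#' if no bin is significant, the largest candidate is used (only the top
#' features survive).
#'
#' @param scores An [hfs_scores()] tibble computed on the training data.
#' @param train,tune Disjoint data frames with the outcome column; `train`
#'   fits the working model, `tune` scores the bins.
#' @param outcome Outcome column name.
#' @param kind Learner backend (or a [learner_spec()]).
#' @param candidates Strictly increasing candidate cutoffs (default
#'   0.5, 0.55, 0.6, 0.65, 0.7).
#' @param n_perm Permutations per bin.
#' @param seed Integer seed.
#' @param hyperparameters Learner overrides.
#' @return A list with the chosen `tau` and a `bins` tibble (edges, sizes,
#'   set importance, p-values).
#' @export
adaptive_cutoff <- function(scores, train, tune, outcome = "y", kind = "svm",
                            candidates = c(0.5, 0.55, 0.6, 0.65, 0.7),
                            n_perm = 100, seed = 1, hyperparameters = list()) {
  stopifnot(inherits(scores, "hfs_scores"))
  tr <- prep_data(as.data.frame(if (inherits(train, "hifit_sim")) train$data else train), outcome)
  tu <- prep_data(as.data.frame(if (inherits(tune, "hifit_sim")) tune$data else tune), outcome)
  spec <- if (inherits(kind, "learner_spec")) kind else {
    learner_spec(kind, resolve_outcome_type(tr$y), hyperparameters, seed)
  }
  anomaly <- scores$anomaly[match(colnames(tr$X), scores$feature)]
  res <- adaptive_cutoff_matrix(anomaly, tr$X, tr$y, tu$X, tu$y, spec,
                                candidates, n_perm, seed)
  res[c("tau", "bins")]
}

#' Screen-then-fit model (one-shot variant)
#'
#' The light-weight alternative to the full nested pipeline: hybrid
#' screening on the training data, a cutoff either tuned on a held-out
#' ninth of the training set ([adaptive_cutoff()]) or fixed (e.g. 0.6 for
#' the Lasso variant), then a single learner fit on the surviving features
#' and evaluation on the test set. If no feature survives, the top
#' \eqn{\lceil\sqrt{p}\rceil} features by anomaly score are used instead
#' (with a warning).
#'
#' @param split A [split_train_test()] result (or any list with `train` and
#'   `test` data frames).
#' @param outcome Outcome column name.
#' @param kind Learner backend.
#' @param tau `"auto"` for the adaptive cutoff, or a fixed value in \[0, 1\].
#' @param candidates,n_perm Passed to [adaptive_cutoff()] when `tau =
#'   "auto"`.
#' @param M,delta,iso_B,iso_psi Screening settings (see [hfs_scores()]).
#' @param hyperparameters Learner overrides.
#' @param seed Integer seed.
#' @return An object of class `s_model`: list with the fitted `model`, the
#'   chosen `tau`, `selected` feature names, the score table and a one-row
#'   `metrics` tibble from the test set.
#' @export
run_s_model <- function(split, outcome = "y", kind = "svm", tau = "auto",
                        candidates = c(0.5, 0.55, 0.6, 0.65, 0.7),
                        n_perm = 100, M = 3, delta = 1e-3, iso_B = 100,
                        iso_psi = NULL, hyperparameters = list(), seed = 1) {
  train <- as_tibble(split$train)
  test <- as_tibble(split$test)
  prep <- prep_data(train, outcome)
  spec <- learner_spec(kind, resolve_outcome_type(prep$y),
                       hyperparameters, derive_seed(seed, "fit"))
  binary <- spec$outcome_type == "binary"

  if (identical(tau, "auto")) {
    idx <- seq_len(nrow(train))
    tune_idx <- withr::with_seed(derive_seed(seed, "tune"), {
      if (binary) {
        unlist(lapply(split(idx, prep$y), function(i) {
          sample(i, round(length(i) / 9))
        }), use.names = FALSE)
      } else {
        sample(idx, round(length(idx) / 9))
      }
    })
    screen_idx <- setdiff(idx, tune_idx)
    scores <- hybrid_scores_matrix(prep$X[screen_idx, , drop = FALSE],
                                   prep$y[screen_idx], M = M, delta = delta,
                                   B = iso_B, psi = iso_psi,
                                   seed = derive_seed(seed, "hfs"))
    ac <- adaptive_cutoff_matrix(scores$anomaly,
                                 prep$X[screen_idx, , drop = FALSE],
                                 prep$y[screen_idx],
                                 prep$X[tune_idx, , drop = FALSE],
                                 prep$y[tune_idx],
                                 spec, candidates, n_perm,
                                 derive_seed(seed, "cutoff"))
    tau <- ac$tau
  } else {
    if (!is.numeric(tau) || tau < 0 || tau > 1) {
      stop_hifit("tau must be \"auto\" or a value in [0, 1]")
    }
    scores <- hybrid_scores_matrix(prep$X, prep$y, M = M, delta = delta,
                                   B = iso_B, psi = iso_psi,
                                   seed = derive_seed(seed, "hfs"))
  }

  sel <- which(scores$anomaly >= tau)
  if (length(sel) == 0) {
    warn("screening selected no feature; falling back to the top ceiling(sqrt(p)) anomaly scores")
    sel <- order(scores$anomaly, decreasing = TRUE)[seq_len(ceiling(sqrt(ncol(prep$X))))]
  }
  model <- fit_learner_matrix(spec, prep$X[, sel, drop = FALSE], prep$y)
  pred <- predict(model, test)
  metrics <- metric_prediction(test[[outcome]], pred, spec$outcome_type)

  structure(
    list(model = model, tau = tau, selected = colnames(prep$X)[sel],
         anomaly = scores$anomaly, metrics = metrics, outcome = outcome),
    class = "s_model"
  )
}

#' @export
print.s_model <- function(x, ...) {
  cat(sprintf("<s_model> %s on %d screened features (tau = %.2f)\n",
              x$model$spec$kind, length(x$selected), x$tau))
  print(x$metrics)
  invisible(x)
}

#' Full screening + importance-refinement pipeline
#'
#' Runs the complete two-stage workflow under a nested K-fold
#' cross-validation that keeps cutoff tuning and importance estimation on
#' data never used for fitting:
#' \enumerate{
#'   \item The samples are split into K folds. For fold k, hybrid screening
#'     scores and all working models are computed on the other K - 1 folds.
#'   \item Fold k is halved; one half tunes the screening cutoff
#'     ([adaptive_cutoff()]) and the other half provides per-sample
#'     permutation-importance scores for the features selected at that
#'     cutoff, then the halves swap roles.
#'   \item Per-sample scores are pooled across all 2K validation halves into
#'     one mean/variance/z-test per feature; features never screened in any
#'     fold get importance 0 and p = 1.
#'   \item The final feature set is every feature with pooled p <
#'     `p_cutoff`; the final model is refit on those features over all
#'     samples.
#' }
#'
#' @param data Data frame (or `hifit_sim`) with outcome and numeric
#'   features; this is the training data (hold out a test set first, e.g.
#'   with [split_train_test()]).
#' @param outcome Outcome column name.
#' @param kind Learner backend for both tuning and importance models.
#' @param outcome_type Inferred when `NULL`.
#' @param K Number of outer folds (default 5).
#' @param n_perm Permutations per importance estimate (default 100).
#' @param p_cutoff Significance cutoff for the final feature set (default
#'   0.1, unadjusted).
#' @param candidates Candidate screening cutoffs.
#' @param M,delta,iso_B,iso_psi Screening settings (see [hfs_scores()]).
#' @param hyperparameters Learner overrides.
#' @param always_keep Feature names exempt from screening (e.g. demographic
#'   covariates); always included in every model and in the final set.
#' @param test_data Optional held-out data frame; when given, prediction
#'   metrics are computed on it.
#' @param seed Integer run seed; all folds, permutations and ensemble
#'   members derive from it.
#' @return An object of class `hifit_result`: `importance` (per-feature
#'   tibble), `final_features`, `final_model`, `fold_records`, `fold_id`,
#'   `metrics` (or NULL) and the run `config`.
#' @export
#' @examples
#' \donttest{
#' sim <- simulate_dataset(n = 200, p = 50, seed = 1)
#' res <- hifit(sim, "y", kind = "svm", K = 2, n_perm = 20, seed = 1)
#' tidy(res)
#' }
hifit <- function(data, outcome = "y", kind = "svm", outcome_type = NULL,
                  K = 5, n_perm = 100, p_cutoff = 0.1,
                  candidates = c(0.5, 0.55, 0.6, 0.65, 0.7),
                  M = 3, delta = 1e-3, iso_B = 100, iso_psi = NULL,
                  hyperparameters = list(), always_keep = NULL,
                  test_data = NULL, seed = 1) {
  if (inherits(data, "hifit_sim")) data <- data$data
  prep <- prep_data(data, outcome)
  X <- prep$X
  y <- prep$y
  n <- nrow(X)
  p <- ncol(X)
  if (K < 2) stop_hifit("K must be at least 2")
  if (n < 10 * K) stop_hifit("need at least 10 samples per fold (n >= 10 K)")
  outcome_type <- resolve_outcome_type(y, outcome_type)
  binary <- outcome_type == "binary"
  spec <- learner_spec(if (inherits(kind, "learner_spec")) kind$kind else kind,
                       outcome_type, hyperparameters, seed)
  keep_idx <- integer(0)
  if (!is.null(always_keep)) {
    keep_idx <- match(always_keep, colnames(X))
    if (anyNA(keep_idx)) {
      stop_hifit(paste("always_keep columns not found:",
                       paste(always_keep[is.na(keep_idx)], collapse = ", ")))
    }
  }

  fold_id <- make_folds(y, K, derive_seed(seed, "folds"), binary)
  score_pool <- vector("list", p)
  records <- list()

  for (k in seq_len(K)) {
    tr <- which(fold_id != k)
    va <- which(fold_id == k)
    scores_k <- hybrid_scores_matrix(
      X[tr, , drop = FALSE], y[tr], outcome_type = outcome_type,
      M = M, delta = delta, B = iso_B, psi = iso_psi,
      seed = derive_seed(seed, "hfs", k), skip = keep_idx
    )
    halves <- split_half(va, y, derive_seed(seed, "half", k), binary)

    for (h in 1:2) {
      tune_idx <- halves[[h]]
      est_idx <- halves[[3 - h]]
      ac <- adaptive_cutoff_matrix(
        scores_k$anomaly, X[tr, , drop = FALSE], y[tr],
        X[tune_idx, , drop = FALSE], y[tune_idx],
        spec, candidates, n_perm,
        derive_seed(seed, "cutoff", k, h), keep_idx
      )
      sel <- sort(union(which(!is.na(scores_k$anomaly) &
                                scores_k$anomaly >= ac$tau), keep_idx))
      if (length(sel) == 0) {
        # nothing reaches the fallback cutoff: keep the top sqrt(p) scorers
        ord <- order(scores_k$anomaly, decreasing = TRUE, na.last = NA)
        sel <- sort(ord[seq_len(min(ceiling(sqrt(p)), length(ord)))])
      }
      model <- fit_learner_matrix(
        working_spec(spec_with_seed(spec, derive_seed(seed, "est", k, h))),
        X[tr, sel, drop = FALSE], y[tr]
      )
      Xe <- X[est_idx, sel, drop = FALSE]
      ye <- y[est_idx]
      for (j in sel) {
        sc <- persample_scores(model, Xe, ye, match(j, sel), n_perm,
                               derive_seed(seed, "perm", k, h, j), binary)
        fk <- paste0(k, ".", h)
        if (is.null(score_pool[[j]])) score_pool[[j]] <- list()
        score_pool[[j]][[fk]] <- sc
      }
      records[[length(records) + 1]] <- tibble(
        fold = k, half = h, n_train = length(tr), n_tune = length(tune_idx),
        n_est = length(est_idx), tau = ac$tau, n_selected = length(sel)
      )
    }
  }

  importance <- dplyr::bind_rows(lapply(seq_len(p), function(j) {
    summarize_half_scores(score_pool[[j]], colnames(X)[j])
  }))
  importance$selected <- importance$p < p_cutoff
  if (length(keep_idx)) importance$selected[keep_idx] <- TRUE

  final_idx <- which(importance$selected)
  final_features <- importance$feature[final_idx]
  final_model <- if (length(final_idx) == 0) {
    warn("no feature passed the importance test; final model is intercept-only")
    const <- if (binary) mean(y) else mean(y)
    new_hifit_model(spec, character(0), fit = const,
                    predict_fn = function(fit, newX) rep(const, nrow(newX)),
                    trivial = TRUE)
  } else {
    fit_learner_matrix(spec_with_seed(spec, derive_seed(seed, "final")),
                       X[, final_idx, drop = FALSE], y)
  }

  result <- structure(
    list(
      importance = importance, final_features = final_features,
      final_model = final_model,
      fold_records = dplyr::bind_rows(records), fold_id = fold_id,
      metrics = NULL,
      config = list(outcome = outcome, kind = spec$kind,
                    outcome_type = outcome_type, K = K, n_perm = n_perm,
                    p_cutoff = p_cutoff, candidates = candidates, M = M,
                    delta = delta, iso_B = iso_B,
                    iso_psi = iso_psi, always_keep = always_keep,
                    seed = seed)
    ),
    class = "hifit_result"
  )
  if (!is.null(test_data)) {
    result$metrics <- evaluate_run(result, test_data)
  }
  result
}

#' Re-threshold the final feature set of a fitted pipeline
#'
#' Recomputes the selected set from the pooled importance table at a new
#' p-value cutoff (raising the cutoff can only grow the set).
#'
#' @param result A [hifit()] result.
#' @param p_cutoff New cutoff.
#' @return Character vector of selected feature names.
#' @export
select_features <- function(result, p_cutoff) {
  stopifnot(inherits(result, "hifit_result"))
  sel <- result$importance$p < p_cutoff
  keep <- result$config$always_keep
  union(result$importance$feature[sel], keep %||% character(0))
}

#' Evaluate a fitted pipeline on held-out data
#'
#' Computes prediction metrics of the final model on a test set and, when
#' the causal feature indices are known (simulation mode), the selection
#' TPR and FDR of the final feature set.
#'
#' @param result A [hifit()] result.
#' @param test_data Data frame containing the outcome and at least every
#'   final feature column.
#' @param causal Optional causal feature indices (positions in the feature
#'   table) or names.
#' @return A one-row tibble of metrics.
#' @export
evaluate_run <- function(result, test_data, causal = NULL) {
  stopifnot(inherits(result, "hifit_result"))
  if (inherits(test_data, "hifit_sim")) test_data <- test_data$data
  outcome <- result$config$outcome
  test_data <- as.data.frame(test_data)
  missing <- setdiff(c(result$final_features, outcome), names(test_data))
  if (length(missing)) {
    stop_hifit(paste("test data lacks columns:", paste(missing, collapse = ", ")))
  }
  pred <- predict(result$final_model, test_data)
  metrics <- metric_prediction(test_data[[outcome]], pred,
                               result$config$outcome_type)
  if (!is.null(causal)) {
    sel <- if (is.numeric(causal)) {
      which(result$importance$feature %in% result$final_features)
    } else {
      result$final_features
    }
    metrics <- dplyr::bind_cols(metric_tpr_fdr(sel, causal), metrics)
  }
  metrics
}

#' @export
print.hifit_result <- function(x, ...) {
  cat(sprintf(
    "<hifit_result> %s backend, K = %d folds, %d permutations\n",
    x$config$kind, x$config$K, x$config$n_perm
  ))
  cat(sprintf("  final features (p < %.2g): %d of %d\n",
              x$config$p_cutoff, length(x$final_features),
              nrow(x$importance)))
  if (length(x$final_features)) {
    cat(" ", paste(utils::head(x$final_features, 15), collapse = ", "))
    if (length(x$final_features) > 15) cat(", ...")
    cat("\n")
  }
  if (!is.null(x$metrics)) {
    cat("  held-out metrics:\n")
    print(x$metrics)
  }
  invisible(x)
}
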