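learner_kinds <- c("svm", "rf", "xgb", "ensemble_dnn", "lasso")

default_hyperparameters <- function(kind, outcome_type, d) {
  switch(kind,
    svm = list(cost = 1, epsilon = 0.1, gamma = 1 / max(d, 1),
               tune = TRUE, tune_folds = 5),
    rf = list(ntree = 500,
              mtry = if (outcome_type == "continuous") max(floor(d / 3), 1)
                     else max(floor(sqrt(d)), 1)),
    xgb = list(eta = 0.3, max_depth = 6, nrounds = 100,
               early_stopping_rounds = 10, holdout = 0.1, tune = TRUE),
    ensemble_dnn = list(n_ensemble = 100, keep_frac = 0.5,
                        hidden = c(50, 30), epochs = 800, batch = 16,
                        lr = 5e-3, patience = 60, l2 = 0.015),
    lasso = list(nfolds = 10)
  )
}

#' Describe a machine-learning backend
#'
#' A learner specification pins the backend (`svm`, `rf`, `xgb`,
#' `ensemble_dnn` or `lasso`), the outcome type, hyperparameters and a seed,
#' so fits are reproducible and interchangeable behind one fit/predict
#' contract.
#'
#' Default hyperparameters: radial SVM with cost and kernel width tuned by
#' 5-fold CV over a small grid around cost 1 / gamma 1/d (`tune = FALSE`
#' pins those values); random forest with 500 trees and mtry `floor(d/3)`
#' (regression) or `floor(sqrt(d))` (classification); gradient boosting
#' with early stopping on a 10\% holdout and a small learning-rate x depth
#' grid searched on it; Lasso with 10-fold cross-validated penalty; and a
#' bagged ensemble of 100 multilayer perceptrons (hidden layers 50/30,
#' ReLU, weight decay 0.015) keeping the best half by out-of-bag loss.
#'
#' @param kind Backend name.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param hyperparameters Named list overriding the defaults above; unknown
#'   names are an error.
#' @param seed Integer seed used by stochastic backends.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(kind = learner_kinds,
                         outcome_type = c("continuous", "binary"),
                         hyperparameters = list(), seed = 1) {
  kind <- match.arg(kind)
  outcome_type <- match.arg(outcome_type)
  known <- names(default_hyperparameters(kind, outcome_type, d = 10))
  bad <- setdiff(names(hyperparameters), known)
  if (length(bad)) {
    stop_hifit(sprintf("unknown hyperparameters for %s: %s (known: %s)",
                       kind, paste(bad, collapse = ", "),
                       paste(known, collapse = ", ")))
  }
  structure(list(kind = kind, outcome_type = outcome_type,
                 hyperparameters = hyperparameters, seed = seed),
            class = "learner_spec")
}

new_hifit_model <- function(spec, features, fit, predict_fn, trivial = FALSE) {
  structure(list(spec = spec, features = features, fit = fit,
                 predict_fn = predict_fn, trivial = trivial),
            class = "hifit_model")
}

#' Fit a machine-learning backend to a feature table
#'
#' Fits the backend named in `kind` (or a full [learner_spec()]) to the
#' numeric feature columns of `data` against the outcome column. All
#' backends share the same contract: `predict()` on the fitted object maps a
#' data frame (or matrix) with the training columns to a numeric vector --
#' predicted values for continuous outcomes, class-1 probabilities for
#' binary ones.
#'
#' @param data Data frame (or `hifit_sim`) with the outcome column and
#'   numeric features.
#' @param outcome Outcome column name.
#' @param kind Backend name, or a `learner_spec` object (then the remaining
#'   arguments are ignored).
#' @param outcome_type Inferred from the outcome when `NULL`.
#' @param hyperparameters Named list of overrides (see [learner_spec()]).
#' @param seed Integer seed.
#' @return A fitted `hifit_model`.
#' @export
#' @examples
#' sim <- simulate_dataset(n = 100, p = 12, seed = 1)
#' fit <- fit_learner(sim, "y", kind = "svm")
#' head(predict(fit, sim$data))
fit_learner <- function(data, outcome = "y", kind = "svm",
                        outcome_type = NULL, hyperparameters = list(),
                        seed = 1) {
  if (inherits(data, "hifit_sim")) data <- data$data
  prep <- prep_data(data, outcome)
  spec <- if (inherits(kind, "learner_spec")) kind else {
    learner_spec(kind, resolve_outcome_type(prep$y, outcome_type),
                 hyperparameters, seed)
  }
  fit_learner_matrix(spec, prep$X, prep$y)
}

# Matrix-interface fit used throughout the pipeline.
fit_learner_matrix <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  if (ncol(X) == 0) stop_hifit("no feature columns to fit on")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop_hifit("non-finite values in the training data")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  binary <- spec$outcome_type == "binary"
  if (binary && !all(y %in% c(0, 1))) stop_hifit("binary outcome must be coded 0/1")

  # degenerate outcome: every backend predicts the constant
  if (stats::sd(y) < .Machine$double.eps) {
    const <- y[1]
    return(new_hifit_model(spec, colnames(X), fit = const,
                           predict_fn = function(fit, newX) {
                             rep(const, nrow(newX))
                           }, trivial = TRUE))
  }

  hp <- modifyList(default_hyperparameters(spec$kind, spec$outcome_type,
                                           ncol(X)),
                   spec$hyperparameters)
  switch(spec$kind,
    svm = fit_svm(spec, X, y, hp, binary),
    rf = fit_rf(spec, X, y, hp, binary),
    xgb = fit_xgb(spec, X, y, hp, binary),
    lasso = fit_lasso_matrix(spec, X, y, hp, binary),
    ensemble_dnn = fit_ensemble_dnn_matrix(spec, X, y, hp, binary)
  )
}

# Radial SVM. By default the cost and kernel width are tuned by CV over a
# small grid around the library defaults (a linear signal needs a much
# smaller gamma than a wiggly one; fixed defaults underfit one or the
# other). `tune = FALSE` pins the given cost/gamma/epsilon.
fit_svm <- function(spec, X, y, hp, binary) {
  yy <- if (binary) factor(y, levels = c(0, 1)) else y
  fit <- withr::with_seed(spec$seed, {
    if (isTRUE(hp$tune) && nrow(X) >= 10 * hp$tune_folds) {
      tn <- e1071::tune.svm(
        X, yy, kernel = "radial",
        gamma = hp$gamma * c(0.1, 0.25, 1, 4),
        cost = c(1, 4, 16, 64), epsilon = hp$epsilon,
        tunecontrol = e1071::tune.control(cross = hp$tune_folds)
      )
      bp <- tn$best.parameters
      e1071::svm(x = X, y = yy, kernel = "radial", cost = bp$cost,
                 epsilon = hp$epsilon, gamma = bp$gamma, probability = binary)
    } else {
      e1071::svm(x = X, y = yy, kernel = "radial", cost = hp$cost,
                 epsilon = hp$epsilon, gamma = hp$gamma, probability = binary)
    }
  })
  predict_fn <- if (binary) {
    function(fit, newX) {
      pr <- predict(fit, newX, probability = TRUE)
      unname(attr(pr, "probabilities")[, "1"])
    }
  } else {
    function(fit, newX) unname(predict(fit, newX))
  }
  new_hifit_model(spec, colnames(X), fit, predict_fn)
}

fit_rf <- function(spec, X, y, hp, binary) {
  yy <- if (binary) factor(y, levels = c(0, 1)) else y
  fit <- withr::with_seed(spec$seed, randomForest::randomForest(
    x = X, y = yy, ntree = hp$ntree, mtry = hp$mtry
  ))
  predict_fn <- if (binary) {
    function(fit, newX) unname(predict(fit, newX, type = "prob")[, "1"])
  } else {
    function(fit, newX) unname(predict(fit, newX))
  }
  new_hifit_model(spec, colnames(X), fit, predict_fn)
}

# Gradient-boosted trees with early stopping on a 10% holdout. By default a
# small (learning rate x depth) grid is searched and the configuration with
# the best holdout loss wins; `tune = FALSE` pins eta/max_depth.
fit_xgb <- function(spec, X, y, hp, binary) {
  n <- nrow(X)
  objective <- if (binary) "binary:logistic" else "reg:squarederror"
  hold_loss <- function(pred, yh) {
    if (binary) {
      ph <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
      -mean(yh * log(ph) + (1 - yh) * log(1 - ph))
    } else {
      mean((yh - pred)^2)
    }
  }
  fit <- withr::with_seed(spec$seed, {
    n_hold <- floor(hp$holdout * n)
    if (n_hold >= 5) {
      hold <- sample(n, n_hold)
      dtrain <- xgboost::xgb.DMatrix(X[-hold, , drop = FALSE], label = y[-hold])
      dval <- xgboost::xgb.DMatrix(X[hold, , drop = FALSE], label = y[hold])
      grid <- if (isTRUE(hp$tune)) {
        expand.grid(eta = c(0.1, 0.3), max_depth = c(2, 3, 6))
      } else {
        data.frame(eta = hp$eta, max_depth = hp$max_depth)
      }
      best <- NULL
      best_loss <- Inf
      for (g in seq_len(nrow(grid))) {
        bst <- xgboost::xgb.train(
          list(objective = objective, eta = grid$eta[g],
               max_depth = grid$max_depth[g], nthread = 1),
          dtrain, nrounds = if (isTRUE(hp$tune)) 500 else hp$nrounds,
          evals = list(val = dval),
          early_stopping_rounds = hp$early_stopping_rounds, verbose = 0
        )
        loss <- hold_loss(predict(bst, dval), y[hold])
        if (loss < best_loss) {
          best_loss <- loss
          best <- bst
        }
      }
      best
    } else {
      xgboost::xgb.train(list(objective = objective, eta = hp$eta,
                              max_depth = hp$max_depth, nthread = 1),
                         xgboost::xgb.DMatrix(X, label = y),
                         nrounds = hp$nrounds, verbose = 0)
    }
  })
  predict_fn <- function(fit, newX) {
    unname(predict(fit, xgboost::xgb.DMatrix(newX)))
  }
  new_hifit_model(spec, colnames(X), fit, predict_fn)
}

fit_lasso_matrix <- function(spec, X, y, hp, binary) {
  if (nrow(X) < 20) stop_hifit("lasso backend needs at least 20 samples")
  padded <- ncol(X) == 1
  Xf <- if (padded) cbind(X, `..pad` = 0) else X
  foldid <- canonical_foldid(Xf, y, hp$nfolds)
  fit <- glmnet::cv.glmnet(Xf, y,
                           family = if (binary) "binomial" else "gaussian",
                           foldid = foldid)
  predict_fn <- function(fit, newX) {
    if (padded) newX <- cbind(newX, `..pad` = 0)
    drop(predict(fit, newX, s = "lambda.min", type = "response"))
  }
  new_hifit_model(spec, colnames(X), fit, predict_fn)
}

#' Fit a cross-validated Lasso baseline
#'
#' L1-penalized (generalized) linear model with the penalty chosen by
#' 10-fold cross-validation at minimum deviance. Fold assignment uses a
#' canonical row ordering so the fit does not depend on row order.
#'
#' @inheritParams fit_learner
#' @return A fitted `hifit_model`.
#' @export
fit_lasso <- function(data, outcome = "y", outcome_type = NULL, seed = 1) {
  fit_learner(data, outcome, kind = "lasso", outcome_type = outcome_type,
              seed = seed)
}

#' @export
predict.hifit_model <- function(object, newdata, ...) {
  newX <- if (is.matrix(newdata)) newdata else {
    df <- as.data.frame(newdata)
    keep <- intersect(names(df), object$features)
    as.matrix(df[keep])
  }
  missing <- setdiff(object$features, colnames(newX))
  if (length(missing)) {
    stop_hifit(paste("missing feature columns:", paste(missing, collapse = ", ")))
  }
  newX <- newX[, object$features, drop = FALSE]
  object$predict_fn(object$fit, newX)
}

#' @export
print.hifit_model <- function(x, ...) {
  cat(sprintf("<hifit_model> %s (%s outcome), %d features%s\n",
              x$spec$kind, x$spec$outcome_type, length(x$features),
              if (x$trivial) " [degenerate: constant prediction]" else ""))
  invisible(x)
}
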