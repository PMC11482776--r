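test_that("all backends honor the fit/predict contract", {
  sim <- simulate_dataset(120, 12, "linear", seed = 1)
  for (kind in c("svm", "rf", "xgb", "lasso")) {
    fit <- fit_learner(sim, "y", kind = kind, seed = 2,
                       hyperparameters = if (kind %in% c("svm", "xgb")) {
                         list(tune = FALSE)
                       } else list())
    pr <- predict(fit, sim$data)
    expect_length(pr, 120)
    expect_true(all(is.finite(pr)))
  }
  bin <- binarize_outcome(sim, seed = 3)
  for (kind in c("svm", "rf", "xgb", "lasso")) {
    fit <- fit_learner(bin, "y", kind = kind, seed = 2,
                       hyperparameters = if (kind %in% c("svm", "xgb")) {
                         list(tune = FALSE)
                       } else list())
    pr <- predict(fit, bin$data)
    expect_true(all(pr >= 0 & pr <= 1))
  }
  expect_error(fit_learner(sim, "y", kind = "nope"))
  expect_error(learner_spec("svm", hyperparameters = list(bogus = 1)),
               "unknown hyperparameters")
})

test_that("a constant outcome yields constant predictions from every backend", {
  X <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("X", 1:5)))
  d <- feature_frame(X, rep(2.5, 40))
  for (kind in c("svm", "rf", "xgb")) {
    fit <- fit_learner(d, "y", kind = kind)
    expect_equal(predict(fit, d), rep(2.5, 40))
  }
})

test_that("prediction needs the training columns and respects their order", {
  sim <- simulate_dataset(80, 12, "linear", seed = 4)
  fit <- fit_learner(sim, "y", kind = "svm", seed = 1,
                     hyperparameters = list(tune = FALSE))
  shuffled <- sim$data[c(".sample", "y", sample(paste0("X", 1:12)))]
  expect_equal(predict(fit, shuffled), predict(fit, sim$data))
  expect_error(predict(fit, sim$data[1:5]), "missing feature columns")
})

test_that("lasso recovers a strong coefficient and ends at the intercept", {
  set.seed(6)
  X <- matrix(rnorm(500 * 50), 500, 50, dimnames = list(NULL, paste0("X", 1:50)))
  y <- 2 * X[, 1] + rnorm(500)
  fit <- fit_lasso(feature_frame(X, y), "y")
  beta <- coef(fit$fit, s = "lambda.min")
  expect_lt(abs(beta["X1", 1] - 2), 0.2)
  # the end of the path is intercept-only
  beta_inf <- coef(fit$fit, s = max(fit$fit$lambda))
  expect_true(all(abs(beta_inf[-1, 1]) < 1e-8))
  fit2 <- fit_lasso(feature_frame(X, y), "y")
  expect_equal(predict(fit, feature_frame(X, y)), predict(fit2, feature_frame(X, y)))
})

test_that("SVM and lasso fits are invariant to training-row order", {
  set.seed(7)
  X <- matrix(rnorm(200 * 10), 200, 10, dimnames = list(NULL, paste0("X", 1:10)))
  y <- X[, 1] + rnorm(200)
  d <- feature_frame(X, y)
  perm <- sample(200)
  for (kind in c("svm", "lasso")) {
    f1 <- fit_learner(d, "y", kind = kind, seed = 1,
                      hyperparameters = if (kind == "svm") list(tune = FALSE) else list())
    f2 <- fit_learner(d[perm, ], "y", kind = kind, seed = 1,
                      hyperparameters = if (kind == "svm") list(tune = FALSE) else list())
    expect_lt(max(abs(predict(f1, d) - predict(f2, d))), 1e-6)
  }
})

test_that("ensemble filtering keeps exactly the stated fraction of networks", {
  sim <- simulate_dataset(100, 10, "linear", seed = 8)
  fit <- fit_ensemble_dnn(sim, "y", seed = 1,
                          hyperparameters = list(n_ensemble = 11,
                                                 keep_frac = 0.5, epochs = 30))
  expect_length(fit$fit$kept, ceiling(0.5 * 11))
  full <- fit_ensemble_dnn(sim, "y", seed = 1,
                           hyperparameters = list(n_ensemble = 6,
                                                  keep_frac = 1, epochs = 30))
  expect_length(full$fit$kept, 6)  # keep_frac 1: plain bagging
  expect_error(fit_ensemble_dnn(sim$data[1:30, ], "y"), "at least 50")
})

test_that("the filtered ensemble beats the median single network on nonlinear data", {
  wins <- sapply(1:8, function(r) {
    sim <- simulate_dataset(300, 10, "nonlinear", seed = 70000 + r)
    sp <- split_train_test(sim, 0.9, seed = 70000 + r)
    fit <- fit_learner(sp$train, "y", kind = "ensemble_dnn", seed = r,
                       hyperparameters = list(n_ensemble = 16))
    Xt <- as.matrix(sp$test[paste0("X", 1:10)])
    ens_mse <- metric_prediction(sp$test$y, predict(fit, sp$test))$mse
    single <- sapply(seq_along(fit$fit$members), function(b) {
      f <- fit$fit
      Z <- sweep(sweep(Xt, 2, f$center), 2, f$scale, "/")
      pr <- drop(hifit:::mlp_predict_cpp(f$members[[b]], Z, FALSE)) *
        f$y_scale + f$y_center
      mean((sp$test$y - pr)^2)
    })
    ens_mse < median(single)
  })
  expect_gte(sum(wins), 7)  # >= 80% of replicates
})
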