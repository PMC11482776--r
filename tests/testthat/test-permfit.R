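test_that("column permutation preserves the multiset and is seeded", {
  set.seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Xp <- permute_column(X, 2, seed = 5)
  expect_equal(sort(Xp[, 2]), sort(X[, 2]))
  expect_identical(Xp[, c(1, 3)], X[, c(1, 3)])
  expect_identical(permute_column(X, 2, seed = 5), Xp)
  expect_false(identical(permute_column(X, 2, seed = 6)[, 2], Xp[, 2]))
})

test_that("a provably ignored feature has zero importance and p = 1", {
  model <- functional_model(function(X) 2 * X[, 1], c("X1", "X2"))
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("X1", "X2")))
  y <- 2 * X[, 1] + rnorm(100)
  row <- feature_importance(model, feature_frame(X, y), "y", "X2",
                            n_perm = 20, seed = 3)
  expect_equal(row$lambda_hat, 0)
  expect_equal(row$se, 0)
  expect_equal(row$p, 1)
})

test_that("importance of a linear effect matches its closed-form expectation", {
  # f(x) = 2 x1, x1 ~ N(0,1): Lambda_1 = E[(2x1 - 2x1')^2] = 8
  model <- functional_model(function(X) 2 * X[, 1], "X1")
  set.seed(4)
  X <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "X1"))
  y <- 2 * X[, 1]                       # exact model, zero residual
  row <- feature_importance(model, feature_frame(X, y), "y", "X1",
                            n_perm = 5, seed = 5)
  expect_lt(abs(row$lambda_hat - 8), 0.35)
  expect_lt(row$p, 1e-10)
})

test_that("the null importance test keeps its type-I error near nominal", {
  p_null <- null_importance_pvalues()
  expect_lt(abs(mean(p_null < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(p_null)) + 0.01)
  # one-sided p-values are approximately uniform under the null
  ks <- suppressWarnings(ks.test(p_null, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("a single-feature set reduces exactly to the per-feature test", {
  model <- functional_model(function(X) X[, 1] + X[, 2]^2, c("X1", "X2"))
  set.seed(6)
  X <- matrix(rnorm(160), 80, 2, dimnames = list(NULL, c("X1", "X2")))
  y <- X[, 1] + X[, 2]^2 + rnorm(80)
  d <- feature_frame(X, y)
  single <- feature_importance(model, d, "y", "X2", n_perm = 15, seed = 7)
  set_one <- set_importance(model, d, "y", "X2", n_perm = 15, seed = 7)
  expect_equal(set_one$lambda_hat, single$lambda_hat)
  expect_equal(set_one$z, single$z)
  expect_error(set_importance(model, d, "y", character(0)), "non-empty")
})

test_that("set importance has power on causal sets and is null on noise sets", {
  model <- functional_model(function(X) X[, 1] + X[, 2] + X[, 3],
                            paste0("X", 1:6))
  hits <- 0
  null_means <- numeric(40)
  for (r in 1:40) {
    set.seed(80000 + r)
    X <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(NULL, paste0("X", 1:6)))
    y <- X[, 1] + X[, 2] + X[, 3] + rnorm(80)
    d <- feature_frame(X, y)
    if (set_importance(model, d, "y", paste0("X", 1:3), n_perm = 20,
                       seed = r)$p < 0.1) hits <- hits + 1
    null_means[r] <- set_importance(model, d, "y", paste0("X", 4:6),
                                    n_perm = 20, seed = r)$lambda_hat
  }
  expect_gte(hits, 38)                  # >= 95% power on the causal set
  expect_lt(abs(mean(null_means)), 0.1) # noise sets average to nothing
})

test_that("averaging more permutations never increases Monte-Carlo variance", {
  model <- functional_model(function(X) 2 * X[, 1], c("X1", "X2"))
  lam <- sapply(c(1, 10, 50), function(np) {
    sapply(1:40, function(r) {
      set.seed(90000 + r)
      X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("X1", "X2")))
      y <- 2 * X[, 1] + rnorm(60)
      feature_importance(model, feature_frame(X, y), "y", "X1",
                         n_perm = np, seed = r)$lambda_hat
    })
  })
  v <- apply(lam, 2, var)
  expect_gte(v[1] * 1.05, v[2])
  expect_gte(v[2] * 1.05, v[3])
})

test_that("binary and continuous scoring agree in sign for a strong feature", {
  set.seed(11)
  X <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("X1", "X2")))
  cont <- functional_model(function(Z) 2 * Z[, 1], c("X1", "X2"))
  yc <- 2 * X[, 1] + rnorm(200)
  bin <- functional_model(function(Z) plogis(2 * Z[, 1]), c("X1", "X2"),
                          outcome_type = "binary")
  yb <- rbinom(200, 1, plogis(2 * X[, 1]))
  lc <- feature_importance(cont, feature_frame(X, yc), "y", "X1",
                           n_perm = 30, seed = 1)$lambda_hat
  lb <- feature_importance(bin, feature_frame(X, yb), "y", "X1",
                           n_perm = 30, seed = 1)$lambda_hat
  expect_gt(lc, 0)
  expect_gt(lb, 0)
})

test_that("permfit tables are well-formed and BH adjustment is optional", {
  sim <- simulate_dataset(150, 12, "linear", seed = 12)
  sp <- split_train_test(sim, 0.8, seed = 12)
  fit <- fit_learner(sp$train, "y", kind = "svm", seed = 1,
                     hyperparameters = list(tune = FALSE))
  tab <- permfit(fit, sp$test, "y", n_perm = 20, seed = 2, adjust = TRUE)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$p_adj >= tab$p - 1e-12))
  expect_identical(tab$lambda_hat,
                   permfit(fit, sp$test, "y", n_perm = 20, seed = 2)$lambda_hat)
})
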