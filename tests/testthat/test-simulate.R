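test_that("seeded generators are bit-reproducible and correctly shaped", {
  for (scenario in c("linear", "nonlinear")) {
    a <- simulate_dataset(60, 15, scenario, seed = 11)
    b <- simulate_dataset(60, 15, scenario, seed = 11)
    expect_identical(a$data, b$data)
    expect_identical(a$causal, 1:10)
    expect_equal(dim(a$data), c(60, 17))  # .sample + y + 15 features
    d <- simulate_dataset(60, 15, scenario, seed = 12)
    expect_false(identical(a$data$y, d$data$y))
  }
  expect_error(simulate_dataset(60, 9), "at least 10")
  expect_error(simulate_dataset(1, 15), "at least 2")
})

test_that("outcomes follow the stated mean functions with unit noise", {
  sim <- simulate_dataset(2000, 12, "linear", seed = 3, beta = rep(1, 10))
  X <- as.matrix(sim$data[paste0("X", 1:12)])
  expect_equal(sim$f, rowSums(X[, 1:10]))
  eps <- sim$data$y - sim$f
  expect_lt(abs(var(eps) - 1), 0.15)
  expect_lt(abs(cor(sim$f, eps)), 0.1)

  nl <- simulate_dataset(2000, 12, "nonlinear", seed = 4)
  Xn <- as.matrix(nl$data[paste0("X", 1:12)])
  f_ref <- rowSums(2 * sin(2 * Xn[, 1:4])) -
    rowSums(2 * log(2 * Xn[, 5:8]^2 + 1)) + Xn[, 9] * exp(Xn[, 10])
  expect_equal(nl$f, f_ref)
  # spot values of the mean function: all-zero row gives 0, (pi/4, 0, ...) gives 2
  z <- rep(0, 12)
  expect_equal(sum(2 * sin(2 * z[1:4])) - sum(2 * log(2 * z[5:8]^2 + 1)) +
                 z[9] * exp(z[10]), 0)
  z[1] <- pi / 4
  expect_equal(2 * sin(2 * z[1]), 2)
})

test_that("linear outcome variance matches the analytic moment of U(1,1.5)", {
  # E[Var(y)] = 10 E[beta^2] + 1 = 10 * 19/12 + 1
  target <- 10 * (19 / 12) + 1
  vars <- sapply(1:200, function(r) {
    sim <- simulate_dataset(200, 10, "linear", seed = 7000 + r,
                            beta = sim_beta(7000 + r))
    var(sim$data$y)
  })
  expect_lt(abs(mean(vars) - target), 0.5)
})

test_that("nonlinear outcome variance matches a direct Monte-Carlo oracle", {
  set.seed(99)
  Xo <- matrix(rnorm(2e5 * 10), ncol = 10)
  oracle <- var(rowSums(2 * sin(2 * Xo[, 1:4])) -
                  rowSums(2 * log(2 * Xo[, 5:8]^2 + 1)) +
                  Xo[, 9] * exp(Xo[, 10]) + rnorm(2e5))
  pooled <- unlist(lapply(1:50, function(r) {
    simulate_dataset(500, 10, "nonlinear", seed = 8000 + r)$data$y
  }))
  expect_lt(abs(var(pooled) / oracle - 1), 0.1)
})

test_that("binarize_outcome follows the logistic link and its limits", {
  sim <- simulate_dataset(300, 12, "linear", seed = 21)
  b0 <- binarize_outcome(sim, scale = 0, seed = 1)
  expect_true(all(b0$data$y %in% c(0, 1)))
  expect_lt(abs(mean(b0$data$y) - 0.5), 0.15)           # coin flips at c = 0
  bL <- binarize_outcome(sim, scale = 100, seed = 1)    # sign limit at large c
  expect_gt(mean(bL$data$y == (sim$f > median(sim$f))), 0.97)
  expect_identical(binarize_outcome(sim, seed = 5)$data$y,
                   binarize_outcome(sim, seed = 5)$data$y)
})

test_that("train/test split partitions exhaustively, stratified for binary", {
  sim <- simulate_dataset(500, 12, "linear", seed = 31)
  sp <- split_train_test(sim, 0.9, seed = 1)
  expect_equal(nrow(sp$train), 450)
  expect_equal(nrow(sp$test), 50)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:500)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_identical(split_train_test(sim, 0.9, seed = 1)$train_idx, sp$train_idx)

  bin <- binarize_outcome(sim, seed = 2)
  spb <- split_train_test(bin, 0.8, seed = 3)
  expect_lt(abs(mean(spb$train$y) - mean(bin$data$y)), 0.05)
  expect_error(split_train_test(data.frame(y = 1), 0.5), "too small")
  expect_error(split_train_test(sim, 1.2), "ratio")
})

test_that("selection metrics implement the TPR/FDR definitions", {
  expect_equal(metric_tpr_fdr(1:10, 1:10), tibble::tibble(tpr = 1, fdr = 0))
  expect_equal(metric_tpr_fdr(c(1:5, 11:15), 1:10),
               tibble::tibble(tpr = 0.5, fdr = 0.5))
  expect_equal(metric_tpr_fdr(integer(0), 1:10),
               tibble::tibble(tpr = 0, fdr = 0))
  expect_error(metric_tpr_fdr(1:3, integer(0)), "non-empty")
})

test_that("prediction metrics match exact cases and the pair-counting AUC oracle", {
  m <- metric_prediction(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mse, 0)
  expect_equal(m$pcc, 1)
  expect_warning(mc <- metric_prediction(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_equal(mc$pcc, 0)
  expect_false(mc$pcc_defined)

  set.seed(5)
  y <- rep(c(0, 1), 5)
  prob <- c(runif(9), prob10 = 0.3)
  # brute force: fraction of concordant (case, control) pairs, ties half
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  auc_oracle <- mean(ifelse(prob[pairs$i] > prob[pairs$j], 1,
                            ifelse(prob[pairs$i] == prob[pairs$j], 0.5, 0)))
  expect_equal(metric_prediction(y, prob, "binary")$auc, auc_oracle)
  expect_equal(metric_prediction(c(0, 0, 1, 1), c(.1, .2, .8, .9))$auc, 1)
})
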