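test_that("polynomial utility recovers exact fits and is centred under the null", {
  set.seed(1)
  x <- rnorm(50)
  expect_equal(poly_utility(x, 3 * x - 1, M = 1), 1)
  expect_equal(poly_utility(x, x^2, M = 2), 1)
  expect_equal(poly_utility(x, x^2, M = 3), 1)
  expect_lt(poly_utility(x, x^2, M = 1), 0.6)   # order too low misses the shape
  # null distribution of the adjusted R^2 is centred at zero
  null_mean <- mean(sapply(1:1000, function(r) {
    set.seed(r)
    poly_utility(rnorm(500), rnorm(500), M = 3)
  }))
  expect_lt(abs(null_mean), 0.005)
  expect_error(poly_utility(x, rep(1, 50)), "constant")
  expect_error(poly_utility(x[1:4], rnorm(4), M = 3), "order-M")
})

test_that("McFadden utility is positive for a real logistic signal", {
  set.seed(2)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(2 * x))
  expect_gt(poly_utility(x, y, M = 1, outcome_type = "binary"), 0.15)
  expect_lt(poly_utility(rnorm(300), y, M = 3, outcome_type = "binary"), 0.05)
})

test_that("kernel partial correlation equals the dense linear-algebra oracle", {
  dense_kpc <- function(x, y, delta) {
    n <- length(y)
    zs <- function(v) (v - mean(v)) / sd(v)
    gk <- function(v) exp(-0.5 * outer(v, v, "-")^2)
    H <- diag(n) - 1 / n
    Kx <- H %*% gk(zs(x)) %*% H
    Ky <- H %*% gk(zs(y)) %*% H
    O <- Kx %*% solve(Kx + n * delta * diag(n))
    sum(diag(t(O) %*% Ky %*% O)) / sum(diag(Ky))
  }
  set.seed(3)
  for (r in 1:5) {
    x <- rnorm(20)
    y <- x^2 + rnorm(20, sd = 0.5)
    for (delta in c(1e-3, 1e-2)) {
      expect_lt(abs(kpc_utility(x, y, delta) - dense_kpc(x, y, delta)), 1e-10)
    }
  }
})

test_that("kernel partial correlation is bounded, invariant, and detects dependence", {
  set.seed(4)
  y <- rnorm(200)
  x <- rnorm(200)
  v <- kpc_utility(x, y)
  expect_gte(v, 0)
  expect_lt(v, 1)
  expect_equal(kpc_utility(rep(2, 200), y), 0)
  # shifting or rescaling either argument changes nothing (z-scoring)
  expect_lt(abs(kpc_utility(3 * x + 5, y) - v), 1e-10)
  expect_lt(abs(kpc_utility(x, -2 * y + 1) - v), 1e-10)
  # self-dependence beats independence
  expect_gt(kpc_utility(y, y), kpc_utility(x, y))
  expect_error(kpc_utility(x, rep(0, 200)), "constant")
  expect_error(kpc_utility(x, y, delta = 0), "positive")
})

test_that("isolation scores follow the path-length normalization", {
  c_psi <- function(m) 2 * (log(m - 1) + 0.5772156649015329) - 2 * (m - 1) / m
  expect_equal(hifit:::iso_score_from_path(c_psi(10), 10L), 0.5)
  expect_equal(hifit:::iso_score_from_path(c_psi(256), 256L), 0.5)
  expect_gt(hifit:::iso_score_from_path(1, 256L), 0.9)  # short path = anomalous
})

test_that("isolation forest flags the outlier and scores duplicates equally", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(18, sd = 0.1), 9, 2), c(10, 10))
  s <- isolation_scores(pts, B = 100, psi = 10, seed = 1)
  expect_equal(which.max(s), 10)
  expect_true(all(s >= 0 & s <= 1))
  # an independent, plainly-recursive implementation agrees on the ranking
  naive_tree <- function(P, idx, depth, hlim) {
    c_psi <- function(m) {
      if (m <= 1) return(0)
      if (m == 2) return(1)
      2 * (log(m - 1) + 0.5772156649015329) - 2 * (m - 1) / m
    }
    rng <- apply(P[idx, , drop = FALSE], 2, range)
    if (length(idx) <= 1 || depth >= hlim || all(rng[1, ] == rng[2, ])) {
      return(function(x) depth + c_psi(length(idx)))
    }
    q <- sample(which(rng[1, ] < rng[2, ]), 1)
    split <- runif(1, rng[1, q], rng[2, q])
    l <- idx[P[idx, q] < split]
    r <- setdiff(idx, l)
    if (!length(l) || !length(r)) {
      return(function(x) depth + c_psi(length(idx)))
    }
    left <- naive_tree(P, l, depth + 1, hlim)
    right <- naive_tree(P, r, depth + 1, hlim)
    function(x) if (x[q] < split) left(x) else right(x)
  }
  set.seed(42)
  paths <- rowMeans(sapply(1:100, function(b) {
    tr <- naive_tree(pts, sample(10), 0, ceiling(log2(10)))
    apply(pts, 1, tr)
  }))
  naive <- 2^(-paths / (2 * (log(9) + 0.5772156649015329) - 2 * 9 / 10))
  expect_equal(which.max(naive), 10)
  expect_gt(cor(s, naive), 0.7)

  dup <- rbind(pts, pts[10, ])
  sd2 <- isolation_scores(dup, B = 50, psi = 8, seed = 2)
  expect_equal(sd2[10], sd2[11])

  set.seed(7)
  cloud <- matrix(rnorm(400), 200, 2)
  expect_lt(abs(mean(isolation_scores(cloud, seed = 3)) - 0.5), 0.1)
  expect_error(isolation_scores(pts[1, , drop = FALSE]), "at least 2")
  expect_error(isolation_scores(pts, psi = 1), "psi")
})

test_that("hybrid scoring is column-equivariant and marks causal features", {
  sim <- simulate_dataset(150, 20, "linear", seed = 9)
  sc <- hfs_scores(sim, "y", seed = 5)
  expect_equal(nrow(sc), 20)
  expect_true(all(sc$rho2 >= 0 & sc$rho2 < 1))
  expect_true(all(sc$anomaly >= 0 & sc$anomaly <= 1))

  # identical columns receive identical utilities and anomaly scores
  d2 <- sim$data
  d2$X20 <- d2$X1
  sc2 <- hfs_scores(d2, "y", seed = 5)
  expect_equal(sc2$rho1[20], sc2$rho1[1])
  expect_equal(sc2$rho2[20], sc2$rho2[1])
  expect_equal(sc2$anomaly[20], sc2$anomaly[1])

  # permuting the feature columns permutes every score identically
  perm <- c(5:20, 1:4)
  dp <- sim$data[c(".sample", "y", paste0("X", perm))]
  scp <- hfs_scores(dp, "y", seed = 5)
  expect_equal(scp$rho1, sc$rho1[perm])
  expect_equal(scp$anomaly, sc$anomaly[perm])
})

test_that("screening stays sharp and tractable at ten thousand features", {
  sim <- simulate_dataset(360, 10000, "linear", seed = 77)
  sc <- hifit:::hybrid_scores_matrix(
    as.matrix(sim$data[paste0("X", 1:10000)]), sim$data$y, seed = 1
  )
  expect_length(sc$anomaly, 10000)
  expect_true(all(sc$rho2 >= 0 & sc$rho2 < 1))
  expect_lt(mean(rank(-sc$anomaly)[1:10]), 100)
})

test_that("threshold selection implements the cutoff rule with monotone sets", {
  sim <- simulate_dataset(120, 15, "linear", seed = 13)
  sc <- hfs_scores(sim, "y", seed = 1)
  sc$anomaly <- c(0.9, 0.3, rep(0.1, 13))
  expect_equal(threshold_select(sc, 0.5)$selected, 1L)
  expect_equal(threshold_select(sc, 0)$selected, 1:15)
  expect_error(threshold_select(sc, 1.1), "tau")
  expect_warning(threshold_select(sc, 0.95), "empty")
  # ties at exactly tau are included
  expect_true(2L %in% threshold_select(sc, 0.3)$selected)
  # raising tau can only shrink the set
  sc2 <- hfs_scores(sim, "y", seed = 2)
  taus <- seq(0, 1, 0.1)
  sets <- lapply(taus, function(t) threshold_select(sc2, t)$selected)
  for (i in seq_along(taus)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})
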