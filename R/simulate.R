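#' Draw the causal-effect vector for the linear scenario
#'
#' The ten linear coefficients are drawn once per simulation study from
#' \eqn{\mathcal{U}(1, 1.5)} and then held fixed across Monte-Carlo
#' replicates; pass the result to [simulate_dataset()] via `beta`.
#'
#' @param seed Integer seed for the (single) coefficient draw.
#' @return Numeric vector of length 10 with entries in \[1, 1.5\].
#' @export
#' @examples
#' sim_beta(1)
sim_beta <- function(seed = 1) {
  withr::with_seed(seed, runif(10, 1, 1.5))
}

#' Simulate a feature table with a linear or nonlinear outcome
#'
#' Generates `n` samples of `p` independent standard-normal features
#' (multivariate normal with identity covariance) and an outcome
#' \deqn{y = \sum_{j=1}^{10} \beta_j x_j + \varepsilon \quad \text{(linear)}}
#' \deqn{y = \sum_{j=1}^{4} 2\sin(2 x_j) - \sum_{j=5}^{8} 2\log(2 x_j^2 + 1)
#'       + x_9 e^{x_{10}} + \varepsilon \quad \text{(nonlinear)}}
#' with \eqn{\varepsilon \sim N(0,1)}. The first ten features are causal;
#' the remaining `p - 10` are noise.
#'
#' @param n Sample count (>= 2).
#' @param p Feature count (>= 10).
#' @param scenario `"linear"` or `"nonlinear"`.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @param beta Optional length-10 coefficient vector for the linear scenario
#'   (entries in \[1, 1.5\]). When absent it is drawn via [sim_beta()] from a
#'   seed derived from `seed`, so pass an explicit `beta` to hold effects
#'   fixed across replicates.
#' @return An object of class `hifit_sim`: a list with `data` (a tibble with
#'   columns `.sample`, `y`, `X1..Xp`), `causal` (indices 1..10), `beta`
#'   (linear scenario only), `f` (the noiseless mean), and the generating
#'   settings.
#' @export
#' @examples
#' sim <- simulate_dataset(n = 100, p = 20, scenario = "linear", seed = 1)
#' sim$data
simulate_dataset <- function(n = 500, p = 500,
                             scenario = c("linear", "nonlinear"),
                             seed = 1, beta = NULL) {
  scenario <- match.arg(scenario)
  if (n < 2) stop_hifit("n must be at least 2")
  if (p < 10) stop_hifit("p must be at least 10 (the model has 10 causal features)")
  if (scenario == "linear") {
    if (is.null(beta)) beta <- sim_beta(derive_seed(seed, "beta"))
    if (length(beta) != 10 || any(beta < 1) || any(beta > 1.5)) {
      stop_hifit("beta must be a length-10 vector with entries in [1, 1.5]")
    }
  } else {
    beta <- NULL
  }

  out <- withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    eps <- rnorm(n)
    list(X = X, eps = eps)
  })
  X <- out$X

  f <- if (scenario == "linear") {
    drop(X[, 1:10, drop = FALSE] %*% beta)
  } else {
    rowSums(2 * sin(2 * X[, 1:4, drop = FALSE])) -
      rowSums(2 * log(2 * X[, 5:8, drop = FALSE]^2 + 1)) +
      X[, 9] * exp(X[, 10])
  }
  y <- f + out$eps

  colnames(X) <- paste0("X", seq_len(p))
  structure(
    list(
      data = tibble(.sample = paste0("S", seq_len(n)), y = y, as_tibble(X)),
      causal = 1:10,
      beta = beta,
      f = f,
      scenario = scenario,
      outcome_type = "continuous",
      n = n, p = p, seed = seed
    ),
    class = "hifit_sim"
  )
}

#' @export
print.hifit_sim <- function(x, ...) {
  cat(sprintf(
    "<hifit_sim> %s scenario, %s outcome: n = %d, p = %d (10 causal), seed = %d\n",
    x$scenario, x$outcome_type, x$n, x$p, x$seed
  ))
  print(x$data, n = 5)
  invisible(x)
}

#' Convert a simulated continuous outcome to a binary one
#'
#' Labels are drawn as \eqn{y_i \sim \mathrm{Bernoulli}(\mathrm{expit}\{c\,
#' (f(x_i) - \mathrm{median}\, f)\})} where \eqn{f} is the noiseless mean of
#' the generating scenario, so `scale = 0` gives coin flips and large `scale`
#' approaches the sign indicator of the centred mean.
#'
#' @param sim A `hifit_sim` object with a continuous outcome.
#' @param scale Link scale \eqn{c \ge 0}.
#' @param seed Integer seed for the Bernoulli draws.
#' @param on_degenerate What to do if a draw yields a single class:
#'   `"resample"` (default, up to 25 redraws) or `"error"`.
#' @return A `hifit_sim` object with `y` in \{0, 1\}.
#' @export
binarize_outcome <- function(sim, scale = 1, seed = 1,
                             on_degenerate = c("resample", "error")) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(inherits(sim, "hifit_sim"))
  if (sim$outcome_type != "continuous") stop_hifit("outcome is already binary")
  if (scale < 0) stop_hifit("scale must be non-negative")
  prob <- plogis(scale * (sim$f - median(sim$f)))
  for (try in seq_len(26)) {
    yb <- withr::with_seed(derive_seed(seed, "binarize", try),
                           rbinom(sim$n, 1, prob))
    if (length(unique(yb)) == 2) break
    if (try == 26 || on_degenerate == "error") {
      stop_hifit("degenerate draw: all samples fell in one class")
    }
  }
  sim$data$y <- as.numeric(yb)
  sim$outcome_type <- "binary"
  sim$binary_scale <- scale
  sim
}

#' Split samples into training and testing sets
#'
#' Partitions the rows of a dataset into disjoint, exhaustive train and test
#' sets. Binary outcomes are split within each class so both parts keep the
#' class balance.
#'
#' @param data A data frame, or a `hifit_sim` object.
#' @param ratio Training fraction in (0, 1); the default 0.9 is the usual
#'   9:1 train/test split.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param outcome Outcome column name (used for stratification).
#' @return A list of class `hifit_split` with tibbles `train` and `test` and
#'   the integer index vectors `train_idx` and `test_idx`.
#' @export
#' @examples
#' sim <- simulate_dataset(n = 100, p = 20, seed = 1)
#' sp <- split_train_test(sim, ratio = 0.9, seed = 2)
#' nrow(sp$train); nrow(sp$test)
split_train_test <- function(data, ratio = 0.9, seed = 1, outcome = "y") {
  if (inherits(data, "hifit_sim")) data <- data$data
  data <- as_tibble(data)
  if (ratio <= 0 || ratio >= 1) stop_hifit("ratio must be in (0, 1)")
  n <- nrow(data)
  y <- data[[outcome]]
  binary <- !is.null(y) && is_binary_vector(y)

  train_idx <- withr::with_seed(seed, {
    if (binary) {
      unlist(lapply(split(seq_len(n), y), function(idx) {
        sample(idx, round(ratio * length(idx)))
      }), use.names = FALSE)
    } else {
      sample(n, round(ratio * n))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(train_idx) == 0 || length(test_idx) == 0) {
    stop_hifit("n too small to populate both the training and testing sets")
  }
  structure(
    list(
      train = data[train_idx, , drop = FALSE],
      test = data[test_idx, , drop = FALSE],
      train_idx = train_idx, test_idx = test_idx
    ),
    class = "hifit_split"
  )
}

#' @export
print.hifit_split <- function(x, ...) {
  cat(sprintf("<hifit_split> %d training / %d testing samples\n",
              nrow(x$train), nrow(x$test)))
  invisible(x)
}
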