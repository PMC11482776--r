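#' Polynomial-regression marginal utility
#'
#' Fits an order-`M` polynomial of one feature against the outcome and
#' returns the adjusted R-squared (continuous outcome) or McFadden's pseudo
#' R-squared (binary outcome, ridge-stabilized logistic fit). The adjusted
#' form can be negative for uninformative features; under the null it is
#' centred near zero.
#'
#' @param x Numeric feature vector.
#' @param y Outcome vector (binary outcomes coded 0/1 with both classes
#'   present).
#' @param M Polynomial order (default 3; captures quadratic/logarithmic/
#'   sinusoidal marginal shapes at moderate n without overfitting).
#' @param outcome_type `"continuous"` or `"binary"`; inferred when `NULL`.
#' @return A single numeric utility \eqn{\rho_{j1}}.
#' @export
#' @examples
#' x <- rnorm(50)
#' poly_utility(x, 3 * x - 1, M = 1)
poly_utility <- function(x, y, M = 3, outcome_type = NULL) {
  n <- length(y)
  if (length(x) != n) stop_hifit("x and y must have equal length")
  if (n <= M + 1) stop_hifit("need n > M + 1 observations for an order-M fit")
  outcome_type <- resolve_outcome_type(y, outcome_type)
  if (stats::sd(y) < .Machine$double.eps) stop_hifit("constant outcome")
  design <- cbind(1, outer(x, seq_len(M), `^`))

  if (outcome_type == "continuous") {
    fit <- stats::lm.fit(design, y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    return(1 - (n - 1) / (n - M - 1) * rss / tss)
  }

  if (length(unique(y)) != 2) stop_hifit("binary outcome must have both classes")
  ll0 <- {
    pbar <- mean(y)
    n * (pbar * log(pbar) + (1 - pbar) * log(1 - pbar))
  }
  llj <- ridge_logistic_loglik(design, y, lambda = 1e-6)
  rho <- 1 - llj$loglik / ll0
  if (!llj$converged) {
    warn("logistic fit did not converge (separation?); utility capped at 1")
    rho <- min(rho, 1)
  }
  rho
}

# Newton/IRLS logistic regression with a small ridge on the non-intercept
# coefficients; returns the (penalty-free) log-likelihood at the penalized
# optimum. The ridge keeps separated fits finite.
ridge_logistic_loglik <- function(design, y, lambda = 1e-6,
                                  maxit = 50, tol = 1e-8) {
  d <- ncol(design)
  pen <- diag(c(0, rep(lambda, d - 1)), d)
  beta <- numeric(d)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(design %*% beta), -30), 30)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    grad <- crossprod(design, y - mu) - pen %*% beta
    hess <- crossprod(design * w, design) + pen
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- pmin(pmax(drop(design %*% beta), -30), 30)
  mu <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
  list(loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)), converged = converged)
}

#' Kernel partial correlation marginal utility
#'
#' The empirical kernel partial correlation between one feature and the
#' outcome,
#' \deqn{\hat\rho_{j2} = \mathrm{tr}(O_j^\top \tilde K_y O_j) /
#'       \mathrm{tr}(\tilde K_y), \qquad
#'       O_j = \tilde K_j (\tilde K_j + n\delta I)^{-1},}
#' where \eqn{\tilde K = H K H} are doubly centred Gaussian kernel matrices
#' (\eqn{k(a,b)=\exp\{-\|a-b\|^2/2\}} on z-scored inputs). The value always
#' lies in \[0, 1) for \eqn{\delta > 0} and is invariant to shifting or
#' rescaling `x` or `y`.
#'
#' @param x Numeric feature vector.
#' @param y Outcome vector (not constant).
#' @param delta Ridge \eqn{\delta > 0} (default 1e-3).
#' @param standardize z-score inputs before kernel evaluation (default TRUE;
#'   the kernel bandwidth is 1 on the standardized scale).
#' @return A single numeric utility \eqn{\hat\rho_{j2} \in [0, 1)}.
#' @export
#' @examples
#' x <- rnorm(50)
#' kpc_utility(x, sin(2 * x) + rnorm(50, sd = 0.1))
kpc_utility <- function(x, y, delta = 1e-3, standardize = TRUE) {
  n <- length(y)
  if (length(x) != n) stop_hifit("x and y must have equal length")
  if (n < 3) stop_hifit("need at least 3 observations")
  if (delta <= 0) stop_hifit("delta must be positive")
  if (stats::sd(y) < .Machine$double.eps) stop_hifit("constant outcome")
  if (standardize) {
    x <- zscore(x)
    y <- zscore(y)
  }
  drop(kpc_scores_cpp(matrix(x, ncol = 1), y, delta, 1e-15))
}

#' Isolation-forest anomaly scores
#'
#' Scores each row of a point cloud by the canonical isolation forest: `B`
#' random binary partition trees are grown on subsamples of size `psi`
#' (without replacement, height limit \eqn{\lceil \log_2 \psi \rceil}), and
#' the anomaly score is
#' \deqn{s(\rho, \psi) = 2^{-\bar h(\rho)/c(\psi)}}
#' with \eqn{\bar h} the average path length (corrected at external nodes by
#' the unsuccessful-search term \eqn{c(m) = 2H(m-1) - 2(m-1)/m}). Points
#' isolated quickly -- here, features whose utility pair sits away from the
#' noise bulk -- score close to 1; the bulk scores near 0.5 or below.
#'
#' @param points Numeric matrix (one row per feature, e.g. the p x 2 matrix
#'   of hybrid utilities).
#' @param B Number of trees (>= 1).
#' @param psi Subsample size per tree (default `min(256, nrow(points))`).
#' @param seed Integer seed.
#' @return Numeric vector of anomaly scores in \[0, 1\].
#' @export
isolation_scores <- function(points, B = 100, psi = NULL, seed = 1) {
  points <- as.matrix(points)
  p <- nrow(points)
  if (p < 2) stop_hifit("need at least 2 points to score")
  psi <- psi %||% min(256L, p)
  if (B < 1) stop_hifit("B must be at least 1")
  if (psi < 2 || psi > p) stop_hifit("psi must be in [2, nrow(points)]")
  # canonical row order so scores do not depend on how the points are listed
  ord <- do.call(order, lapply(seq_len(ncol(points)), function(j) points[, j]))
  out <- numeric(p)
  out[ord] <- withr::with_seed(
    seed, iso_scores_cpp(points[ord, , drop = FALSE],
                         as.integer(B), as.integer(psi))
  )
  out
}

# Matrix-interface hybrid scoring used by the pipeline (no tibble overhead).
hybrid_scores_matrix <- function(X, y, outcome_type = NULL, M = 3,
                                 delta = 1e-3, B = 100, psi = NULL, seed = 1,
                                 skip = integer(0)) {
  p <- ncol(X)
  outcome_type <- resolve_outcome_type(y, outcome_type)
  cols <- setdiff(seq_len(p), skip)
  rho1 <- rep(NA_real_, p)
  for (j in cols) {
    rho1[j] <- tryCatch(
      poly_utility(X[, j], y, M = M, outcome_type = outcome_type),
      hifit_error = function(e) {
        stop_hifit(sprintf("column %d ('%s'): %s", j,
                           colnames(X)[j] %||% j, conditionMessage(e)))
      }
    )
  }
  Z <- apply(X[, cols, drop = FALSE], 2, zscore)
  rho2 <- rep(NA_real_, p)
  rho2[cols] <- drop(kpc_scores_cpp(Z, zscore(y), delta, 1e-15))
  pts <- cbind(rho1[cols], rho2[cols])
  anomaly <- rep(NA_real_, p)
  anomaly[cols] <- isolation_scores(pts, B = B,
                                    psi = min(psi %||% min(256L, length(cols)),
                                              length(cols)),
                                    seed = seed)
  list(rho1 = rho1, rho2 = rho2, anomaly = anomaly,
       M = M, delta = delta, B = B,
       psi = min(psi %||% min(256L, length(cols)), length(cols)),
       outcome_type = outcome_type)
}

#' Hybrid marginal utilities and anomaly scores (HFS scoring stage)
#'
#' Computes, for every feature, the polynomial-regression utility
#' \eqn{\rho_{j1}} ([poly_utility()]) and the kernel partial correlation
#' \eqn{\hat\rho_{j2}} ([kpc_utility()]), then scores the p x 2 utility
#' cloud with an isolation forest ([isolation_scores()]): features whose
#' utility pair is anomalous relative to the noise bulk get scores near 1.
#'
#' @param data A data frame (or `hifit_sim`) containing the outcome column
#'   and numeric feature columns.
#' @param outcome Name of the outcome column.
#' @param outcome_type `"continuous"` or `"binary"`; inferred when `NULL`.
#' @param M,delta Polynomial order and KPC ridge (see the utility functions).
#' @param B,psi Isolation-forest tree count and subsample size.
#' @param seed Integer seed for the isolation forest.
#' @return An object of class `hfs_scores`: a tibble with one row per
#'   feature (`feature`, `rho1`, `rho2`, `anomaly`) carrying the scoring
#'   settings as attributes.
#' @seealso [threshold_select()], [hfs_screen()]
#' @export
#' @examples
#' sim <- simulate_dataset(n = 120, p = 30, seed = 1)
#' hfs_scores(sim, "y", seed = 1)
hfs_scores <- function(data, outcome = "y", outcome_type = NULL, M = 3,
                       delta = 1e-3, B = 100, psi = NULL, seed = 1) {
  if (inherits(data, "hifit_sim")) data <- data$data
  prep <- prep_data(data, outcome)
  if (ncol(prep$X) < 2) stop_hifit("need at least 2 feature columns")
  sc <- hybrid_scores_matrix(prep$X, prep$y, outcome_type = outcome_type,
                             M = M, delta = delta, B = B, psi = psi,
                             seed = seed)
  out <- tibble(
    feature = colnames(prep$X),
    rho1 = sc$rho1, rho2 = sc$rho2, anomaly = sc$anomaly
  )
  attr(out, "settings") <- sc[c("M", "delta", "B", "psi", "outcome_type")]
  class(out) <- c("hfs_scores", class(out))
  out
}

#' Threshold anomaly scores into a screened feature set
#'
#' Applies the selection rule \eqn{\hat S = \{j : s(\rho_j, \psi) \ge \tau\}}
#' (ties at exactly \eqn{\tau} are included).
#'
#' @param scores An `hfs_scores` tibble.
#' @param tau Cutoff in \[0, 1\].
#' @return An object of class `hfs_screen`: list with `tau`, `selected`
#'   (integer indices), `features` (selected names) and the score table.
#' @export
threshold_select <- function(scores, tau) {
  stopifnot(inherits(scores, "hfs_scores"))
  if (!is.numeric(tau) || length(tau) != 1 || tau < 0 || tau > 1) {
    stop_hifit("tau must be a single value in [0, 1]")
  }
  selected <- which(scores$anomaly >= tau)
  if (length(selected) == 0) {
    warn("no feature passed the cutoff; the screened set is empty")
  }
  structure(
    list(tau = tau, selected = selected,
         features = scores$feature[selected], scores = scores),
    class = "hfs_screen"
  )
}

#' Screen features by hybrid scoring at a fixed cutoff
#'
#' Convenience wrapper: [hfs_scores()] followed by [threshold_select()].
#' For a data-driven cutoff inside a fitted pipeline, see [adaptive_cutoff()]
#' and [hifit()].
#'
#' @inheritParams hfs_scores
#' @param tau Anomaly-score cutoff (default 0.6, the fixed cutoff used with
#'   the Lasso variant of the screening-then-fit workflow).
#' @return An `hfs_screen` object.
#' @export
#' @examples
#' sim <- simulate_dataset(n = 150, p = 40, seed = 1)
#' sc <- hfs_screen(sim, "y", tau = 0.6, seed = 1)
#' sc$features
hfs_screen <- function(data, outcome = "y", tau = 0.6, ...) {
  threshold_select(hfs_scores(data, outcome, ...), tau)
}

#' @export
print.hfs_screen <- function(x, ...) {
  cat(sprintf("<hfs_screen> tau = %.3f: %d of %d features selected\n",
              x$tau, length(x$selected), nrow(x$scores)))
  if (length(x$selected)) {
    cat(" ", paste(utils::head(x$features, 20), collapse = ", "))
    if (length(x$features) > 20) cat(", ...")
    cat("\n")
  }
  invisible(x)
}
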