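# Bagged-and-filtered ensemble of multilayer perceptrons. Each member is
# trained on a bootstrap resample with early stopping on its out-of-bag
# samples; members are ranked by out-of-bag loss and only the best
# `keep_frac` fraction contributes to the ensemble prediction, which teases
# out poorly converged networks.

fit_ensemble_dnn_matrix <- function(spec, X, y, hp, binary) {
  n <- nrow(X)
  if (n < 50) stop_hifit("ensemble_dnn needs at least 50 samples")

  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  if (binary) {
    ys <- y
    y_center <- 0; y_scale <- 1
  } else {
    y_center <- mean(y); y_scale <- stats::sd(y)
    ys <- (y - y_center) / y_scale
  }

  B <- hp$n_ensemble
  members <- vector("list", B)
  oob_loss <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    res <- withr::with_seed(derive_seed(spec$seed, "dnn", b), {
      boot <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), boot)
      if (length(oob) < 2) oob <- sample.int(n, max(2, floor(0.1 * n)))
      mlp_train_cpp(Xs, ys, as.integer(hp$hidden), binary,
                    boot - 1L, oob - 1L,
                    as.integer(hp$epochs), as.integer(hp$batch),
                    hp$lr, as.integer(hp$patience), hp$l2)
    })
    members[[b]] <- res[c("W", "b")]
    oob_loss[b] <- res$val_loss
  }
  if (!any(is.finite(oob_loss))) {
    stop_hifit(sprintf(
      "all %d networks diverged (out-of-bag losses all non-finite)", B))
  }
  n_keep <- ceiling(hp$keep_frac * B)
  kept <- order(oob_loss)[seq_len(n_keep)]

  fit <- list(members = members, kept = kept, oob_loss = oob_loss,
              center = center, scale = scale_,
              y_center = y_center, y_scale = y_scale, binary = binary)
  predict_fn <- function(fit, newX) {
    Z <- sweep(sweep(newX, 2, fit$center), 2, fit$scale, "/")
    preds <- vapply(fit$kept, function(b) {
      drop(mlp_predict_cpp(fit$members[[b]], Z, fit$binary))
    }, numeric(nrow(Z)))
    if (nrow(Z) == 1) preds <- matrix(preds, nrow = 1)
    drop(rowMeans(preds)) * fit$y_scale + fit$y_center
  }
  new_hifit_model(spec, colnames(X), fit, predict_fn)
}

#' Fit the bagged-and-filtered neural-network ensemble
#'
#' Trains `n_ensemble` bootstrap multilayer perceptrons (two ReLU hidden
#' layers of 50 and 30 units by default, Adam optimizer, early stopping on
#' out-of-bag loss), then keeps the best `keep_frac` fraction by out-of-bag
#' performance; the ensemble prediction is the mean over the kept networks.
#' With `keep_frac = 1` this reduces to plain bagging.
#'
#' @inheritParams fit_learner
#' @param hyperparameters Overrides for `n_ensemble` (100), `keep_frac`
#'   (0.5), `hidden` (c(50, 30)), `epochs` (800), `batch` (16), `lr` (5e-3),
#'   `patience` (60), `l2` (0.015, the weight decay that keeps single
#'   networks from memorizing moderate-n training sets).
#' @return A fitted `hifit_model`; `fit$kept` holds the indices of the
#'   retained networks.
#' @export
fit_ensemble_dnn <- function(data, outcome = "y", outcome_type = NULL,
                             hyperparameters = list(), seed = 1) {
  fit_learner(data, outcome, kind = "ensemble_dnn",
              outcome_type = outcome_type,
              hyperparameters = hyperparameters, seed = seed)
}
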