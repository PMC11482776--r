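# Shared fixtures; heavier simulation results are computed once per test run
# and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A model with a known prediction function: lets permutation-importance
# properties be checked against closed-form oracles without fitting noise.
functional_model <- function(fn, features, outcome_type = "continuous") {
  hifit:::new_hifit_model(
    spec = learner_spec("svm", outcome_type),
    features = features,
    fit = fn,
    predict_fn = function(fit, newX) fit(newX)
  )
}

feature_frame <- function(X, y) {
  d <- as.data.frame(X)
  d$y <- y
  d
}

# Ten linear-scenario pipeline replicates at p = 500 with the SVM backend,
# shared by the selection-quality invariants and the acceptance checks.
pipeline_replicates <- function() {
  fixture("pipeline_reps", function() {
    beta <- sim_beta(1001)
    lapply(1:10, function(r) {
      sim <- simulate_dataset(500, 500, "linear", seed = 6000 + r, beta = beta)
      sp <- split_train_test(sim, 0.9, seed = 6000 + r)
      res <- hifit(sp$train, "y", kind = "svm", K = 5, n_perm = 100,
                   hyperparameters = list(tune = FALSE), seed = 6100 + r)
      sel <- which(res$importance$p < 0.1)
      list(result = res, selected = sel,
           tpr_fdr = metric_tpr_fdr(sel, 1:10))
    })
  })
}

# Oracle learner benchmarks (10 causal features only, 9:1 split).
oracle_runs <- function(scenario, kind, reps = 30) {
  fixture(paste("oracle", scenario, kind, reps, sep = "_"), function() {
    beta <- if (scenario == "linear") sim_beta(hifit:::derive_seed(1, "beta"))
    t(sapply(seq_len(reps), function(r) {
      sim <- simulate_dataset(500, 10, scenario, seed = 40000 + r, beta = beta)
      sp <- split_train_test(sim, 0.9, seed = 40000 + r)
      fit <- fit_learner(sp$train, "y", kind = kind, seed = r)
      met <- metric_prediction(sp$test$y, predict(fit, sp$test))
      c(mse = met$mse, pcc = met$pcc)
    }))
  })
}

# Null permutation-importance p-values from a fixed functional model that
# uses a feature the outcome does not depend on.
null_importance_pvalues <- function(reps = 500, n_val = 100, n_perm = 30) {
  fixture(paste("null_p", reps, sep = "_"), function() {
    model <- functional_model(function(X) X[, 1] + 0.3 * X[, 2],
                              c("X1", "X2"))
    sapply(seq_len(reps), function(r) {
      set.seed(50000 + r)
      X <- matrix(rnorm(n_val * 2), n_val, 2,
                  dimnames = list(NULL, c("X1", "X2")))
      y <- X[, 1] + rnorm(n_val)
      feature_importance(model, feature_frame(X, y), "y", "X2",
                         n_perm = n_perm, seed = 60000 + r)$p
    })
  })
}
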