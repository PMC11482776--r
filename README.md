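# hifit

Two-stage identification of outcome-associated biomarkers in
high-dimensional biomedical data, with honest per-feature inference and a
final predictive model.

Omics studies (microbiome, transcriptome, proteome) measure thousands of
features on hundreds of samples. Flexible learners capture the nonlinear
and interactive effects such data carry, but they degrade badly when noise
features dominate, and they give no per-feature inferential statement.
`hifit` implements a screening-then-testing workflow for analysts who need
both a compact, defensible feature list and a predictive model:

1. **Hybrid feature screening (HFS).** Every feature gets a pair of
   marginal utilities — the adjusted R² (or McFadden pseudo-R²) of an
   order-*M* polynomial fit, and a kernel partial correlation
   ρ̂<sub>j2</sub> = tr(O<sub>j</sub>ᵀ K̃<sub>y</sub> O<sub>j</sub>) / tr(K̃<sub>y</sub>),
   O<sub>j</sub> = K̃<sub>j</sub>(K̃<sub>j</sub> + nδI)⁻¹ — and an isolation
   forest on the p × 2 utility cloud turns the pair into an anomaly score
   s(ρ<sub>j</sub>, ψ) = 2^(−h̄/c(ψ)) ∈ [0, 1]. Features scoring above a
   cutoff τ (data-driven, candidates 0.5–0.7) survive.
2. **Permutation feature-importance testing (PermFIT).** On held-out
   validation data, the importance of feature *j* is the mean per-sample
   increase in loss when its column is permuted,
   Λ̂<sub>j</sub> = mean<sub>i</sub> Λ̂<sub>ij</sub>, tested one-sided with
   z = Λ̂<sub>j</sub> / (σ̂<sub>j</sub>/√n<sub>V</sub>) ~ N(0, 1) under the
   null. A nested K-fold cross-validation keeps cutoff tuning and
   importance estimation on samples the models never saw; features with
   pooled p < 0.1 form the final set, on which the final model is refit.

Backends: radial SVM, random forest, gradient-boosted trees, a
bagged-and-filtered neural-network ensemble, and a Lasso baseline — all
behind one `fit_learner()` / `predict()` contract. Simulation generators
for the linear and nonlinear benchmark scenarios, TPR/FDR and prediction
metrics, broom-style `tidy()`/`glance()`, `autoplot()` methods and a small
CLI (`inst/cli/hifit`) are included. See the methods vignette
(`vignettes/hifit-methods.Rmd`) for the full model account, defaults and
known limitations.

## Worked example

Simulate the linear benchmark scenario (500 samples, 500 features of which
the first ten are causal), hold out a test set, and run the full pipeline
with the SVM backend:

```r
library(hifit)

sim <- simulate_dataset(n = 500, p = 500, scenario = "linear", seed = 7)
sp  <- split_train_test(sim, ratio = 0.9, seed = 7)

res <- hifit(sp$train, outcome = "y", kind = "svm",
             K = 5, n_perm = 100, p_cutoff = 0.1, seed = 7)
res
#> <hifit_result> svm backend, K = 5 folds, 100 permutations
#>   final features (p < 0.1): 13 of 500
#>   X1, X2, X3, X4, X5, X6, X7, X8, X9, X10, X176, X206, X386

evaluate_run(res, sp$test, causal = 1:10)
#> # A tibble: 1 × 5
#>     tpr   fdr   mse   pcc pcc_defined
#>   <dbl> <dbl> <dbl> <dbl> <lgl>
#> 1     1 0.231  1.03 0.976 TRUE
```

All ten causal features are recovered (TPR 1) along with three false
positives; the final SVM predicts the held-out outcome with mean squared
error 1.03 (the irreducible noise variance is 1) and Pearson correlation
0.98. `tidy(res)` returns the full importance table (feature,
Λ̂, SE, z, p, selected) and `autoplot(res)` draws it; note that with the
raw p < 0.1 rule the realized FDR of the final set runs well above the
nominal level in null-dominated settings — see the vignette's limitations
section and the `adjust = TRUE` option of `permfit()`.

The same stages are available à la carte: `hfs_scores()` /
`threshold_select()` for screening alone, `adaptive_cutoff()` for the
data-driven τ, `run_s_model()` for the one-shot screen-then-fit variant,
`permfit()` for importance testing of any fitted model.

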