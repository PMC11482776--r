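#' Selection quality of a feature set
#'
#' True-positive rate (selected causal / all causal) and false-discovery
#' rate (selected noise / all selected) of a selected feature set against
#' the known causal set. An empty selection has, by convention, TPR 0 and
#' FDR 0 (nothing was discovered, falsely or otherwise).
#'
#' @param selected Integer indices (or names) of the selected features.
#' @param causal Integer indices (or names) of the causal features
#'   (non-empty).
#' @return A one-row tibble with columns `tpr` and `fdr`.
#' @export
#' @examples
#' metric_tpr_fdr(c(1:5, 11:15), 1:10)
metric_tpr_fdr <- function(selected, causal) {
  if (length(causal) == 0) stop_hifit("causal set must be non-empty")
  if (length(selected) == 0) return(tibble(tpr = 0, fdr = 0))
  tibble(
    tpr = length(intersect(selected, causal)) / length(causal),
    fdr = length(setdiff(selected, causal)) / length(selected)
  )
}

# AUC as the rank (Wilcoxon) statistic; ties count one half.
auc_rank <- function(y_true, prob) {
  r <- rank(prob)
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop_hifit("AUC needs both classes present")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prediction accuracy metrics
#'
#' For a continuous outcome, mean squared error and the Pearson correlation
#' between predictions and observations; for a binary outcome, accuracy at
#' the 0.5 probability threshold and the rank-statistic AUC.
#'
#' @param y_true Observed outcomes.
#' @param y_pred Predicted values (class-1 probabilities for binary).
#' @param outcome_type `"continuous"` or `"binary"`; inferred from `y_true`
#'   when `NULL`.
#' @return A one-row tibble: `mse`, `pcc`, `pcc_defined` (continuous) or
#'   `accuracy`, `auc` (binary). A constant prediction vector has no defined
#'   correlation; `pcc` is then reported as 0 with `pcc_defined = FALSE` and
#'   a warning.
#' @export
#' @examples
#' metric_prediction(c(1, 2, 3), c(1.1, 1.9, 3.2))
metric_prediction <- function(y_true, y_pred, outcome_type = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_hifit("y_true and y_pred must have equal length")
  }
  outcome_type <- resolve_outcome_type(y_true, outcome_type)
  if (outcome_type == "binary") {
    return(tibble(
      accuracy = mean((y_pred >= 0.5) == (y_true == 1)),
      auc = auc_rank(y_true, y_pred)
    ))
  }
  mse <- mean((y_true - y_pred)^2)
  if (stats::sd(y_pred) < .Machine$double.eps) {
    warn("constant predictions: Pearson correlation undefined, reported as 0")
    return(tibble(mse = mse, pcc = 0, pcc_defined = FALSE))
  }
  tibble(mse = mse, pcc = cor(y_true, y_pred), pcc_defined = TRUE)
}
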