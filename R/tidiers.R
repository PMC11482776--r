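#' Tidy the per-feature score table of a screening result
#'
#' @param x An `hfs_screen` object.
#' @param ... Unused.
#' @return A tibble with one row per feature: both marginal utilities, the
#'   anomaly score, and whether the feature passed the cutoff.
#' @method tidy hfs_screen
#' @export
tidy.hfs_screen <- function(x, ...) {
  out <- as_tibble(x$scores)
  out$selected <- seq_len(nrow(out)) %in% x$selected
  out
}

#' One-row summary of a screening result
#'
#' @param x An `hfs_screen` object.
#' @param ... Unused.
#' @method glance hfs_screen
#' @export
glance.hfs_screen <- function(x, ...) {
  tibble(tau = x$tau, n_features = nrow(x$scores),
         n_selected = length(x$selected))
}

#' Tidy the pooled importance table of a fitted pipeline
#'
#' @param x A [hifit()] result.
#' @param ... Unused.
#' @return The per-feature importance tibble (`feature`, `lambda_hat`,
#'   `se`, `z`, `p`, `n_val`, `selected`).
#' @method tidy hifit_result
#' @export
tidy.hifit_result <- function(x, ...) {
  as_tibble(x$importance)
}

#' One-row summary of a fitted pipeline
#'
#' @param x A [hifit()] result.
#' @param ... Unused.
#' @method glance hifit_result
#' @export
glance.hifit_result <- function(x, ...) {
  out <- tibble(
    kind = x$config$kind, outcome_type = x$config$outcome_type,
    K = x$config$K, n_perm = x$config$n_perm, p_cutoff = x$config$p_cutoff,
    n_features = nrow(x$importance),
    n_selected = length(x$final_features), seed = x$config$seed
  )
  if (!is.null(x$metrics)) out <- dplyr::bind_cols(out, x$metrics)
  out
}

#' Tidy a learner fit
#'
#' @param x A fitted `hifit_model`.
#' @param ... Unused.
#' @return A tibble listing the training features.
#' @method tidy hifit_model
#' @export
tidy.hifit_model <- function(x, ...) {
  tibble(feature = x$features)
}

#' @method glance hifit_model
#' @export
glance.hifit_model <- function(x, ...) {
  tibble(kind = x$spec$kind, outcome_type = x$spec$outcome_type,
         n_features = length(x$features), trivial = x$trivial)
}
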