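# broom-style tidiers for the fitted objects.

#' Tidy a random-forest fit
#'
#' One row per hyperparameter configuration with its validation accuracy
#' and a flag for the selected configuration.
#'
#' @param x A `bafdep_rf`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bafdep_rf <- function(x, ...) {
  out <- tibble::as_tibble(x$grid_results)
  out$selected <- out$n_estimators == x$best_params$n_estimators &
    (out$max_depth %in% x$best_params$max_depth |
       (is.na(out$max_depth) & is.na(x$best_params$max_depth))) &
    out$min_samples_leaf == x$best_params$min_samples_leaf
  out
}

#' One-row test-set summary of a random-forest fit
#'
#' @param x A `bafdep_rf`.
#' @param ... Unused.
#' @return A tibble with confusion counts, accuracy, TPR, FPR, AUROC.
#' @export
glance.bafdep_rf <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    accuracy = m$accuracy, auroc = m$auroc, tpr = m$tpr, fpr = m$fpr,
    tp = m$tp, tn = m$tn, fp = m$fp, fn = m$fn,
    n_test = m$tp + m$tn + m$fp + m$fn
  )
}

#' Tidy a bootstrapped ridge fit
#'
#' One row per feature: averaged coefficient, rank, and the bootstrap
#' standard deviation of the per-iteration coefficients.
#'
#' @param x A `bafdep_ridge`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.bafdep_ridge <- function(x, ...) {
  sds <- apply(x$iterations, 2, sd)
  dplyr::mutate(x$coefficients, bootstrap_sd = as.numeric(sds[.data$feature]))
}

#' One-row summary of a bootstrapped ridge fit
#'
#' @param x A `bafdep_ridge`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.bafdep_ridge <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha, n_iter = x$n_iter,
    subsample_fraction = x$subsample_fraction,
    n_features = nrow(x$coefficients)
  )
}
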