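# Feature-importance framework: binary ChIP-overlap feature matrix,
# class-balanced random-forest classification of accessibility loss with a
# fixed hyperparameter grid, dual importance metrics (MDI + permutation),
# and bootstrapped ridge regression on the quantitative log2 fold change.

#' Pick one ChIP experiment per target by FRiP
#'
#' Among candidate experiments for each target, selects the one with the
#' highest Fraction of Reads in Peaks; ties go to the lexicographically
#' smallest accession.
#'
#' @param candidates Tibble with `target`, `accession`, `frip`.
#' @return Tibble with one row per target (`target`, `accession`, `frip`).
#' @export
select_by_frip <- function(candidates) {
  if (nrow(candidates) == 0) abort("no candidate experiments supplied")
  if (any(is.na(candidates$frip))) {
    bad <- unique(candidates$target[is.na(candidates$frip)])
    abort(paste0("candidate(s) without a FRiP score for target(s): ",
                 paste(bad, collapse = ", ")))
  }
  candidates |>
    dplyr::group_by(.data$target) |>
    dplyr::arrange(dplyr::desc(.data$frip), .data$accession, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Binary peak-by-feature overlap matrix
#'
#' Cell (i, f) is 1 iff peak i overlaps at least one interval of feature f's
#' ChIP peak set (>= 1 bp, half-open coordinates).
#'
#' @param peaks Interval tibble of ATAC peaks.
#' @param chip Named list of interval tibbles, one per chromatin feature.
#' @return Tibble with a `peak` column followed by one 0/1 column per
#'   feature.
#' @export
build_feature_matrix <- function(peaks, chip) {
  peaks <- validate_intervals(peaks)
  if (is.null(names(chip)) || anyDuplicated(names(chip))) {
    abort("chip must be a named list with unique feature names")
  }
  cols <- lapply(chip, function(iv) as.integer(overlaps_any(peaks, iv)))
  dplyr::bind_cols(tibble::tibble(peak = peaks$name), tibble::as_tibble(cols))
}

fm_matrix <- function(fm) {
  m <- as.matrix(fm[, setdiff(names(fm), "peak"), drop = FALSE])
  rownames(m) <- fm$peak
  m
}

#' Class-balance by undersampling and split 70:15:15
#'
#' The majority class is randomly undersampled (seeded) to the minority
#' size; the balanced rows are then randomly partitioned into train,
#' validation, and test sets with floor rounding, remainder to train.
#'
#' @param labels Logical/0-1 vector, one per row of the feature matrix.
#' @param ratios Numeric triple summing to 1 (default `c(.70, .15, .15)`).
#' @param seed Integer seed for undersampling and partitioning.
#' @return List of integer row indices: `train`, `validation`, `test`.
#' @export
balance_and_split <- function(labels, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  labels <- as.logical(labels)
  pos <- which(labels)
  neg <- which(!labels)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("both classes must be non-empty for balancing")
  }
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3) {
    abort("ratios must be three numbers summing to 1")
  }
  with_seed(derive_seed(seed, "balance_split"), {
    k <- min(length(pos), length(neg))
    keep <- c(
      if (length(pos) > k) pos[sample.int(length(pos), k)] else pos,
      if (length(neg) > k) neg[sample.int(length(neg), k)] else neg
    )
    keep <- keep[sample.int(length(keep))]
    n <- length(keep)
    n_val <- floor(ratios[2] * n)
    n_test <- floor(ratios[3] * n)
    n_train <- n - n_val - n_test
    list(
      train = sort(keep[seq_len(n_train)]),
      validation = sort(keep[seq(n_train + 1, length.out = n_val)]),
      test = sort(keep[seq(n_train + n_val + 1, length.out = n_test)])
    )
  })
}

#' The random-forest hyperparameter grid
#'
#' @return Tibble over `n_estimators` {50, 100, 200, 300} x `max_depth`
#'   {unlimited, 10, 20} x `min_samples_leaf` {1, 2}.
#' @export
rf_default_grid <- function() {
  tidyr::expand_grid(
    n_estimators = c(50L, 100L, 200L, 300L),
    max_depth = c(NA_integer_, 10L, 20L),
    min_samples_leaf = c(1L, 2L)
  )
}

binary_metrics <- function(truth, predicted) {
  tp <- sum(predicted & truth)
  tn <- sum(!predicted & !truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_
  )
}

#' ROC curve points over class-probability thresholds
#'
#' @param score Numeric classifier scores (higher = more positive).
#' @param truth Logical true labels.
#' @return Tibble of `(fpr, tpr)` points from (0,0) to (1,1).
#' @export
roc_points <- function(score, truth) {
  truth <- as.logical(truth)
  thresholds <- sort(unique(score), decreasing = TRUE)
  pts <- vapply(thresholds, function(t) {
    pred <- score >= t
    c(sum(pred & !truth) / max(1, sum(!truth)),
      sum(pred & truth) / max(1, sum(truth)))
  }, numeric(2))
  tibble::tibble(
    fpr = c(0, pts[1, ], 1),
    tpr = c(0, pts[2, ], 1)
  )
}

#' Trapezoidal AUROC
#'
#' Integrates the ROC curve by the trapezoid rule; equal to the rescaled
#' Mann-Whitney U statistic (ties counted one half).
#'
#' @param score,truth As in [roc_points()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, truth) {
  pts <- roc_points(score, truth)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

fit_ranger <- function(x, y, params, seed) {
  ranger::ranger(
    x = x, y = factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos")),
    num.trees = params$n_estimators,
    max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
    min.node.size = params$min_samples_leaf,
    probability = TRUE, importance = "impurity",
    seed = seed, num.threads = 1
  )
}

predict_prob <- function(fit, x) {
  as.numeric(stats::predict(fit, data = x)$predictions[, "pos"])
}

#' Grid-searched random forest with held-out test metrics
#'
#' Fits every grid configuration on the training split, scores accuracy on
#' the validation split, selects the best configuration (ties broken toward
#' fewer trees, then shallower depth, then larger leaf size), refits it, and
#' reports confusion counts, accuracy, TPR/FPR, ROC points, and trapezoidal
#' AUROC on the held-out test split.
#'
#' @param fm Feature matrix from [build_feature_matrix()].
#' @param labels Logical response, one per row of `fm` (TRUE = accessibility
#'   lost / BAF-dependent).
#' @param splits Index list from [balance_and_split()].
#' @param grid Hyperparameter tibble (default [rf_default_grid()]).
#' @param seed Integer seed controlling forest randomness.
#' @return A `bafdep_rf` object: fitted model, best parameters, per-config
#'   validation accuracies, and test-set metrics.
#' @export
train_rf <- function(fm, labels, splits, grid = rf_default_grid(), seed = 1L) {
  x <- as.data.frame(fm_matrix(fm))
  labels <- as.logical(labels)
  if (nrow(grid) == 0) abort("empty hyperparameter grid")
  for (s in c("train", "validation", "test")) {
    if (length(unique(labels[splits[[s]]])) < 2) {
      abort(paste0("split '", s, "' contains a single class"))
    }
  }
  rf_seed <- derive_seed(seed, "rf")
  xt <- x[splits$train, , drop = FALSE]
  yt <- labels[splits$train]
  xv <- x[splits$validation, , drop = FALSE]
  yv <- labels[splits$validation]

  grid$validation_accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_ranger(xt, yt, grid[i, ], rf_seed)
    binary_metrics(yv, predict_prob(fit, xv) >= 0.5)$accuracy
  }, numeric(1))

  depth_key <- ifelse(is.na(grid$max_depth), Inf, grid$max_depth)
  best_i <- order(-grid$validation_accuracy, grid$n_estimators, depth_key,
                  -grid$min_samples_leaf)[1]
  best <- grid[best_i, ]
  fit <- fit_ranger(xt, yt, best, rf_seed)

  xs <- x[splits$test, , drop = FALSE]
  ys <- labels[splits$test]
  prob <- predict_prob(fit, xs)
  metrics <- binary_metrics(ys, prob >= 0.5)
  metrics$roc <- roc_points(prob, ys)
  metrics$auroc <- auroc(prob, ys)

  structure(
    list(
      model = fit,
      best_params = best[, c("n_estimators", "max_depth", "min_samples_leaf")],
      grid_results = grid,
      metrics = metrics,
      splits = splits,
      test_probabilities = prob,
      seed = seed
    ),
    class = "bafdep_rf"
  )
}

#' @export
print.bafdep_rf <- function(x, ...) {
  cat("Random-forest accessibility-loss classifier\n")
  cat(sprintf(
    "  best grid point: %d trees, depth %s, min leaf %d\n",
    x$best_params$n_estimators,
    ifelse(is.na(x$best_params$max_depth), "unlimited", x$best_params$max_depth),
    x$best_params$min_samples_leaf
  ))
  cat(sprintf("  test accuracy %.3f, AUROC %.3f\n",
              x$metrics$accuracy, x$metrics$auroc))
  invisible(x)
}

#' Dual random-forest feature importances
#'
#' MDI (impurity) importance normalized to sum 1, plus permutation
#' importance: the mean decrease in test-set accuracy over `n_repeats`
#' seeded permutations of each feature column.
#'
#' @param rf A `bafdep_rf` from [train_rf()].
#' @param fm Feature matrix used to fit it.
#' @param labels Response vector used to fit it.
#' @param test_idx Row indices scored (default the object's test split).
#' @param n_repeats Permutations per feature (default 10).
#' @param seed Integer seed for the permutations.
#' @return Tibble `feature`, `mdi`, `permutation_importance`.
#' @export
compute_importances <- function(rf, fm, labels, test_idx = rf$splits$test,
                                n_repeats = 10L, seed = rf$seed) {
  x <- as.data.frame(fm_matrix(fm))
  labels <- as.logical(labels)
  mdi_raw <- rf$model$variable.importance
  mdi <- if (sum(mdi_raw) > 0) mdi_raw / sum(mdi_raw) else mdi_raw

  xs <- x[test_idx, , drop = FALSE]
  ys <- labels[test_idx]
  base_acc <- binary_metrics(ys, predict_prob(rf$model, xs) >= 0.5)$accuracy
  perm <- with_seed(derive_seed(seed, "permutation_importance"), {
    vapply(names(x), function(f) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        xp <- xs
        xp[[f]] <- xp[[f]][sample.int(nrow(xp))]
        base_acc - binary_metrics(ys, predict_prob(rf$model, xp) >= 0.5)$accuracy
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  tibble::tibble(
    feature = names(x),
    mdi = as.numeric(mdi[names(x)]),
    permutation_importance = as.numeric(perm)
  )
}

#' Bootstrapped ridge regression on quantitative accessibility change
#'
#' Features are standardized (zero mean, unit variance; zero-variance
#' columns receive coefficient 0). For each of `n_iter` seeded bootstrap
#' iterations, a `subsample_fraction` row subset is fitted by L2-penalized
#' least squares with penalty strength `alpha` (intercept unpenalized), and
#' the per-feature coefficients are averaged across iterations. Features are
#' ranked by the averaged coefficient: the most positive predict retained
#' accessibility, the most negative predict accessibility loss.
#'
#' @param fm Feature matrix from [build_feature_matrix()].
#' @param response Numeric response (log2 fold change), one per row.
#' @param alpha Ridge penalty strength (default 1.0).
#' @param n_iter Bootstrap iterations (default 10).
#' @param subsample_fraction Fraction of rows per iteration (default 0.7).
#' @param seed Integer seed for the subsampling.
#' @param n_top Size of the reported extreme-feature lists (default 15).
#' @return A `bafdep_ridge` object with `coefficients` (tibble `feature`,
#'   `beta`, `rank`), the per-iteration coefficient matrix, and the top /
#'   bottom feature lists.
#' @export
fit_ridge_bootstrap <- function(fm, response, alpha = 1.0, n_iter = 10L,
                                subsample_fraction = 0.7, seed = 1L,
                                n_top = 15L) {
  x <- fm_matrix(fm)
  if (nrow(x) < 2) abort("ridge regression needs at least two rows")
  if (any(!is.finite(response))) abort("response must be finite")
  mu <- colMeans(x)
  sdev <- apply(x, 2, sd)
  keep <- sdev > 0
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdev[keep], "/")

  p <- ncol(xs)
  betas <- matrix(0, nrow = n_iter, ncol = ncol(x),
                  dimnames = list(NULL, colnames(x)))
  with_seed(derive_seed(seed, "ridge_bootstrap"), {
    n <- nrow(xs)
    m <- max(2L, floor(subsample_fraction * n))
    for (k in seq_len(n_iter)) {
      idx <- if (m >= n) seq_len(n) else sample.int(n, m)
      xb <- xs[idx, , drop = FALSE]
      yb <- response[idx]
      xb <- sweep(xb, 2, colMeans(xb))
      yb <- yb - mean(yb)
      beta_k <- solve(crossprod(xb) + diag(alpha, p), crossprod(xb, yb))
      betas[k, keep] <- as.numeric(beta_k)
    }
  })
  beta <- colMeans(betas)
  coefs <- tibble::tibble(
    feature = colnames(x), beta = as.numeric(beta)
  ) |>
    dplyr::arrange(dplyr::desc(.data$beta)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(
    list(
      coefficients = coefs,
      iterations = betas,
      alpha = alpha, n_iter = n_iter,
      subsample_fraction = subsample_fraction,
      top_features = head(coefs$feature, n_top),
      bottom_features = rev(utils::tail(coefs$feature, n_top))
    ),
    class = "bafdep_ridge"
  )
}

#' @export
print.bafdep_ridge <- function(x, ...) {
  cat(sprintf(
    "Bootstrapped ridge regression (alpha = %g, %d x %d%% subsets)\n",
    x$alpha, x$n_iter, round(100 * x$subsample_fraction)
  ))
  cat("  most negative (predict accessibility loss):",
      paste(head(x$bottom_features, 5), collapse = ", "), "...\n")
  invisible(x)
}
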