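test_that("FRiP selection takes the maximum with lexicographic ties", {
  cand <- tibble::tibble(
    target = c("TFX", "TFX", "TFY", "TFZ", "TFZ"),
    accession = c("ENC2", "ENC1", "ENC9", "ENCB", "ENCA"),
    frip = c(0.3, 0.5, 0.2, 0.4, 0.4)
  )
  got <- select_by_frip(cand)
  expect_equal(got$accession[got$target == "TFX"], "ENC1")
  expect_equal(got$accession[got$target == "TFY"], "ENC9")
  expect_equal(got$accession[got$target == "TFZ"], "ENCA")

  cand$frip[1] <- NA
  expect_error(select_by_frip(cand), "TFX")
})

test_that("feature matrix cells are 1 iff any interval overlaps", {
  peaks <- genomic_intervals("chr1", 100L, 200L, name = "pk")
  chip <- list(
    inside = genomic_intervals("chr1", 150L, 160L),
    abut = genomic_intervals("chr1", 200L, 300L),
    none = genomic_intervals(character(), integer(), integer())
  )
  fm <- build_feature_matrix(peaks, chip)
  expect_equal(fm$inside, 1L)
  expect_equal(fm$abut, 0L)
  expect_equal(fm$none, 0L)
})

test_that("balancing undersamples the majority class and splits 70:15:15", {
  labels <- c(rep(TRUE, 100), rep(FALSE, 40))
  sp <- balance_and_split(labels, seed = 3)
  all_idx <- c(sp$train, sp$validation, sp$test)
  expect_equal(length(all_idx), 80)
  expect_equal(sum(labels[all_idx]), 40)

  labels2 <- rep(c(TRUE, FALSE), 500)
  sp2 <- balance_and_split(labels2, seed = 3)
  expect_equal(lengths(sp2[c("train", "validation", "test")]),
               c(train = 700L, validation = 150L, test = 150L))
  expect_equal(length(intersect(sp2$train, sp2$test)), 0)

  expect_identical(balance_and_split(labels2, seed = 3), sp2)
  expect_false(identical(balance_and_split(labels2, seed = 4), sp2))
  expect_error(balance_and_split(rep(TRUE, 10)), "classes")
})

test_that("a perfectly separating feature yields accuracy and AUROC 1", {
  set.seed(5)
  n <- 400
  labels <- rep(c(TRUE, FALSE), n / 2)
  fm <- tibble::tibble(
    peak = sprintf("p%03d", 1:n),
    oracle = as.integer(labels),
    noise = rbinom(n, 1, 0.5)
  )
  sp <- balance_and_split(labels, seed = 1)
  rf <- train_rf(fm, labels, sp, grid = rf_default_grid()[1, ], seed = 1)
  expect_equal(rf$metrics$accuracy, 1)
  expect_equal(rf$metrics$auroc, 1)
})

test_that("confusion counts give the accuracy formula", {
  m <- bafdep:::binary_metrics(
    truth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    predicted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  expect_equal(m$tp, 3)
  expect_equal(m$tn, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 0)
  expect_equal(m$accuracy, 5 / 6)
  expect_equal(m$tpr, 1)
  expect_equal(m$fpr, 1 / 3)
})

test_that("trapezoidal AUROC equals the pairwise Mann-Whitney statistic", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    truth <- runif(n) < 0.5
    if (length(unique(truth)) < 2) next
    score <- round(runif(n), sample(c(1, 2), 1)) # force ties sometimes
    expect_equal(auroc(score, truth), bf_auroc(score, truth))
  }
})

test_that("labels independent of features give chance-level AUROC", {
  set.seed(23)
  n <- 2000
  fm <- dplyr::bind_cols(
    tibble::tibble(peak = sprintf("p%04d", 1:n)),
    tibble::as_tibble(setNames(
      lapply(1:10, function(i) rbinom(n, 1, 0.3)), sprintf("f%02d", 1:10)
    ))
  )
  labels <- runif(n) < 0.5
  sp <- balance_and_split(labels, seed = 2)
  rf <- train_rf(fm, labels, sp, grid = rf_default_grid()[c(1, 12), ], seed = 2)
  expect_gt(rf$metrics$auroc, 0.40)
  expect_lt(rf$metrics$auroc, 0.60)
})

test_that("importances find a planted feature among decoys", {
  set.seed(29)
  n <- 2000
  planted <- rbinom(n, 1, 0.5)
  decoys <- lapply(1:20, function(i) rbinom(n, 1, 0.5))
  fm <- dplyr::bind_cols(
    tibble::tibble(peak = sprintf("p%04d", 1:n), signal = planted,
                   constant = 0L),
    tibble::as_tibble(setNames(decoys, sprintf("d%02d", 1:20)))
  )
  labels <- as.logical(rbinom(n, 1, ifelse(planted == 1, 0.9, 0.1)))
  sp <- balance_and_split(labels, seed = 5)
  rf <- train_rf(fm, labels, sp, grid = rf_default_grid()[7, ], seed = 5)
  imp <- compute_importances(rf, fm, labels, seed = 5)
  expect_equal(sum(imp$mdi), 1, tolerance = 1e-9)
  expect_equal(imp$feature[which.max(imp$mdi)], "signal")
  expect_equal(imp$feature[which.max(imp$permutation_importance)], "signal")
  expect_equal(imp$permutation_importance[imp$feature == "constant"], 0)
})

test_that("ridge bootstrap handles degenerate inputs per contract", {
  set.seed(37)
  n <- 200
  fm <- tibble::tibble(
    peak = sprintf("p%03d", 1:n),
    a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.5), flat = 1L
  )
  zero <- fit_ridge_bootstrap(fm, rep(0, n), seed = 1)
  expect_true(all(zero$coefficients$beta == 0))

  y <- rnorm(n)
  full <- fit_ridge_bootstrap(fm, y, subsample_fraction = 1.0, seed = 1)
  expect_true(all(apply(full$iterations, 2, function(col) length(unique(col)) == 1)))
  # closed-form single fit on the standardized design
  x <- scale(as.matrix(fm[, c("a", "b")]))
  beta_ref <- solve(crossprod(x) + diag(1.0, 2), crossprod(x, y - mean(y)))
  got <- full$coefficients$beta[match(c("a", "b"), full$coefficients$feature)]
  expect_equal(got, as.numeric(beta_ref), tolerance = 1e-8)
  expect_equal(full$coefficients$beta[full$coefficients$feature == "flat"], 0)

  expect_error(fit_ridge_bootstrap(fm[1, ], 1), "two rows")
})

test_that("ridge recovers a planted linear signal with the right sign", {
  set.seed(41)
  n <- 5000
  x <- lapply(1:15, function(i) rbinom(n, 1, 0.4))
  fm <- dplyr::bind_cols(
    tibble::tibble(peak = sprintf("p%04d", 1:n)),
    tibble::as_tibble(setNames(x, sprintf("x%02d", 1:15)))
  )
  y <- 2 * x[[7]] + rnorm(n, 0, 0.1)
  fit <- fit_ridge_bootstrap(fm, y, seed = 9)
  expect_equal(fit$coefficients$feature[1], "x07")
  expect_gt(fit$coefficients$beta[1], 0)
})
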