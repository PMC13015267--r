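test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  a <- simulate_perturbation_dataset(cfg)
  b <- simulate_perturbation_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$truth, b$truth)

  ea <- simulate_expression_tables(cfg)
  eb <- simulate_expression_tables(cfg)
  expect_identical(ea$counts, eb$counts)
  expect_identical(ea$tissue_tpm, eb$tissue_tpm)

  la <- simulate_pchic_links(cfg, genes = ea$truth$gene, cres = a$peaks)
  lb <- simulate_pchic_links(cfg, genes = ea$truth$gene, cres = a$peaks)
  expect_identical(la$links, lb$links)
})

test_that("writing a simulation to disk is byte-stable", {
  cfg <- small_config(seed = 5)
  sim <- simulate_perturbation_dataset(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(sim, d1)
  write_simulation(sim, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f)),
      info = f
    )
  }
})

test_that("null configuration gives treated/vehicle count ratio near 1", {
  cfg <- synthetic_config(
    seed = 3, n_peaks = 2000, n_chroms = 2, chrom_length = 1e7,
    class_effects = c(promoter = 0, active_enhancer = 0, primed_enhancer = 0,
                      poised_enhancer = 0, ctcf_bound = 0, unclassified = 0),
    feature_effects = rep(0, 55), lfc_noise_sd = 0,
    depth_factors = rep(1, 6)
  )
  sim <- simulate_perturbation_dataset(cfg)
  veh <- rowMeans(sim$counts[, sim$design$condition == "vehicle"])
  trt <- rowMeans(sim$counts[, sim$design$condition == "treated"])
  expect_gt(mean(trt) / mean(veh), 0.97)
  expect_lt(mean(trt) / mean(veh), 1.03)
})

test_that("class effects order true fold changes as configured", {
  sim <- simulate_perturbation_dataset(small_config(seed = 9))
  tr <- sim$truth
  expect_lt(
    mean(tr$true_log2fc[tr$cre_class == "primed_enhancer"]),
    mean(tr$true_log2fc[tr$cre_class == "active_enhancer"])
  )
  expect_lt(
    mean(tr$true_log2fc[tr$cre_class == "active_enhancer"]),
    mean(tr$true_log2fc[tr$cre_class == "promoter"])
  )
})

test_that("overlap-derived feature matrix reconstructs planted memberships", {
  sim <- simulate_perturbation_dataset(small_config(seed = 2))
  fm <- build_feature_matrix(sim$peaks, sim$chip)
  feats <- names(sim$chip)
  got <- as.matrix(fm[, feats])
  want <- as.matrix(sim$truth[, feats])
  expect_identical(unname(got), unname(want))
})

test_that("peaks never overlap and every record has a truth entry", {
  sim <- simulate_perturbation_dataset(small_config(seed = 4))
  self <- intersect_sets(sim$peaks, sim$peaks)
  expect_true(all(self$query_index == self$subject_index))
  expect_setequal(sim$truth$name, sim$peaks$name)
  expect_setequal(rownames(sim$counts), sim$peaks$name)
})

test_that("empirical log2 count ratios regress on truth with slope near 1", {
  cfg <- synthetic_config(seed = 6, n_peaks = 3000, n_chroms = 3,
                          baseline_mean = 200, depth_factors = rep(1, 6))
  sim <- simulate_perturbation_dataset(cfg)
  veh <- rowMeans(sim$counts[, sim$design$condition == "vehicle"])
  trt <- rowMeans(sim$counts[, sim$design$condition == "treated"])
  emp <- log2((trt + 0.5) / (veh + 0.5))
  slope <- coef(lm(emp ~ sim$truth$true_log2fc))[2]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
})

test_that("configs that cannot fit the peaks are rejected", {
  expect_error(
    simulate_perturbation_dataset(
      synthetic_config(n_peaks = 50000, n_chroms = 1, chrom_length = 1e6)
    ),
    "cannot be placed"
  )
  expect_error(synthetic_config(dispersion = 0), "dispersion")
  expect_error(synthetic_config(feature_membership_prob = 1.2), "probabilities")
  expect_error(synthetic_config(feature_effects = c(1, 2)), "length")
})

test_that("invariant genes have true log2FC exactly zero", {
  expr <- simulate_expression_tables(small_config(seed = 8))
  expect_true(all(expr$truth$true_log2fc[expr$truth$invariant] == 0))
  expect_gt(sum(expr$truth$invariant), 0)
})

test_that("tissue regimes hit the tau closed forms", {
  expr <- simulate_expression_tables(small_config(seed = 8))
  tau <- compute_tau(expr$tissue_tpm)
  regime <- expr$truth$tau_regime[match(tau$gene, expr$truth$gene)]
  expect_true(all(abs(tau$tau[regime == "single"] - 1) < 1e-9))
  expect_true(all(abs(tau$tau[regime == "uniform"]) < 1e-9))
  graded <- tau$tau[regime == "graded"]
  expect_true(all(graded > 0 & graded < 1))
})

test_that("link distances stay in bounds and zero coupling means background matching", {
  cfg <- synthetic_config(seed = 10, n_links = 5000, link_coupling_prob = 0,
                          n_peaks = 1000, n_chroms = 2)
  sim <- simulate_perturbation_dataset(cfg)
  pl <- simulate_pchic_links(cfg, genes = sprintf("G%05d", 1:500), cres = sim$peaks)
  expect_true(all(pl$links$distance >= cfg$link_distance_range[1]))
  expect_true(all(pl$links$distance <= cfg$link_distance_range[2]))
  expect_false(any(pl$links$matched))

  # matched-by-chance frequency approximates the product of marginal rates
  gx <- pl$links$gene %in% pl$genes$name[pl$genes$inducible]
  stim_of_gene <- pl$genes$stimulus[match(pl$links$gene, pl$genes$name)]
  stim_of_cre <- pl$cres$stimulus[match(pl$links$cre, pl$cres$name)]
  same <- gx & !is.na(stim_of_cre) & stim_of_gene == stim_of_cre
  # P(cre matches a given gene's stimulus) ~ rate of one specific stimulus
  cre_rate_a <- mean(pl$cres$inducible & pl$cres$stimulus %in% "stimA", na.rm = TRUE)
  background <- mean(gx) * cre_rate_a
  expect_lt(abs(mean(same, na.rm = TRUE) - background), 0.03)
})

test_that("coupled links put inducible genes on same-stimulus inducible cREs", {
  cfg <- synthetic_config(seed = 10, n_links = 5000, link_coupling_prob = 0.5,
                          n_peaks = 1000, n_chroms = 2)
  sim <- simulate_perturbation_dataset(cfg)
  pl <- simulate_pchic_links(cfg, genes = sprintf("G%05d", 1:500), cres = sim$peaks)
  expect_gt(mean(pl$links$matched), 0.05)
  m <- pl$links[pl$links$matched, ]
  stim_gene <- pl$genes$stimulus[match(m$gene, pl$genes$name)]
  stim_cre <- pl$cres$stimulus[match(m$cre, pl$cres$name)]
  expect_true(all(stim_gene == stim_cre))
})
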