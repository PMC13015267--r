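fake_diff <- function(features, lfc, fdr) {
  tibble::tibble(feature = features, log2fc = lfc, fdr = fdr)
}

test_that("inducible sets apply thresholds and partition by timepoint", {
  u <- c("g1", "g2", "g3", "g4")
  d1 <- fake_diff(u, c(1.0, 0.3, 2.0, -2.0), c(0.5, 0.01, 0.01, 0.01))
  d6 <- fake_diff(u, c(1.0, 0.3, 2.0, 0.0), c(0.01, 0.01, 0.01, 0.9))
  got <- define_inducible_sets(d1, d6)
  expect_equal(got$category[got$member == "g1"], "6h_only")
  expect_false("g2" %in% got$member) # below fold-change threshold
  expect_equal(got$category[got$member == "g3"], "both")
  expect_equal(sum(got$member == "g3"), 1)
  expect_false("g4" %in% got$member) # down, not up

  down <- define_inducible_sets(d1, d6, direction = "down")
  expect_equal(down$member, "g4")
  expect_equal(down$category, "1h_only")

  expect_error(
    define_inducible_sets(d1, fake_diff(c(u[1:3], "other"), rep(1, 4), rep(0.01, 4))),
    "symmetric difference: 2"
  )
})

test_that("link enrichment reproduces the cross-product odds ratio", {
  # 10 links both-inducible, 5 gene-only, 2 cre-only, 8 neither -> OR 8
  links <- tibble::tibble(
    gene = c(sprintf("ig%02d", c(1:10, 1:5)), sprintf("og%02d", 1:10)),
    cre = c(sprintf("ic%02d", 1:10), sprintf("oc%02d", 1:5),
            sprintf("ic%02d", 11:12), sprintf("oc%02d", 6:13))
  )
  got <- test_link_enrichment(links, sprintf("ig%02d", 1:10), sprintf("ic%02d", 1:12))
  expect_equal(got$both, 10)
  expect_equal(got$gene_only, 5)
  expect_equal(got$cre_only, 2)
  expect_equal(got$neither, 8)
  expect_equal(got$odds_ratio, 8)

  empty_sets <- test_link_enrichment(links, character(), sprintf("ic%02d", 1:12))
  expect_true(is.na(empty_sets$odds_ratio))
  expect_match(empty_sets$note, "zero margin")

  expect_error(test_link_enrichment(links[0, ], "a", "b"), "empty")
})

test_that("matched coupling beats mismatched pairs on simulated links", {
  cfg <- synthetic_config(seed = 14, n_links = 5000, link_coupling_prob = 0.5,
                          n_peaks = 1000, n_chroms = 2)
  sim <- simulate_perturbation_dataset(cfg)
  pl <- simulate_pchic_links(cfg, genes = sprintf("G%05d", 1:500), cres = sim$peaks)
  gene_sets <- split(pl$genes$name[pl$genes$inducible],
                     pl$genes$stimulus[pl$genes$inducible])
  cre_sets <- split(pl$cres$name[pl$cres$inducible],
                    pl$cres$stimulus[pl$cres$inducible])
  enr <- link_enrichment_pairs(pl$links, gene_sets, cre_sets)
  matched <- enr$odds_ratio[enr$matched]
  mismatched <- enr$odds_ratio[!enr$matched]
  expect_gt(min(matched), max(mismatched))
})

test_that("per-gene aggregation takes the median and excludes delta-less genes", {
  links <- tibble::tibble(
    gene = c("g1", "g1", "g1", "g2", "g3"),
    cre = c("c1", "c2", "c3", "c4", "c_nodata")
  )
  cre_deltas <- tibble::tibble(cre = c("c1", "c2", "c3", "c4"),
                               delta = c(-2, -1, 0, 0.5))
  gene_deltas <- tibble::tibble(gene = c("g1", "g2", "g3"),
                                delta = c(-1.5, 0.2, 0))
  expect_message(
    got <- aggregate_gene_effect_and_correlate(links, cre_deltas, gene_deltas),
    "excluded 1"
  )
  ge <- got$gene_effects
  expect_equal(ge$median_cre_delta[ge$gene == "g1"], -1)
  expect_equal(ge$median_cre_delta[ge$gene == "g2"], 0.5)
  expect_false("g3" %in% ge$gene)
})

test_that("distance deciles hold 100 links each for 1000 distinct distances", {
  set.seed(8)
  links <- tibble::tibble(
    gene = sprintf("g%04d", 1:1000),
    cre = sprintf("c%04d", 1:1000),
    distance = sample.int(1e6, 1000)
  )
  gene_fc <- tibble::tibble(gene = links$gene, log2fc = rnorm(1000))
  got <- distance_binned_effect(links, gene_fc, sprintf("c%04d", 1:300))
  expect_equal(nrow(got), 10)
  expect_true(all(got$n_inducible + got$n_other == 100))

  one_distance <- dplyr::mutate(links, distance = 1000L)
  deg <- distance_binned_effect(one_distance, gene_fc, sprintf("c%04d", 1:300))
  expect_equal(nrow(deg), 1)

  expect_error(distance_binned_effect(links[1:5, ], gene_fc, "c0001", n_bins = 10),
               "fewer links")
})

test_that("stratified comparison bins into deciles and detects a planted shift", {
  set.seed(44)
  n <- 1000
  df <- tibble::tibble(
    group = rep(c("primed", "active"), each = n / 2),
    covariate = runif(n),
    response = rnorm(n, 0, 0.3) - ifelse(group == "primed", 1, 0)
  )
  got <- stratified_group_comparison(df, group, covariate, response)
  expect_equal(nrow(got$bins), 10)
  expect_true(all(got$bins$n_a + got$bins$n_b == 100))
  expect_lt(got$max_adjusted_p, 0.001)
})

test_that("bins lacking a group are dropped from the Bonferroni family", {
  df <- tibble::tibble(
    group = c(rep("a", 50), rep("b", 50)),
    covariate = c(seq_len(50), 51:100), # groups segregate by covariate
    response = rnorm(100)
  )
  expect_message(
    got <- stratified_group_comparison(df, group, covariate, response, n_bins = 10),
    "lacked one group"
  )
  expect_lt(got$n_evaluable_bins, 10)
})

test_that("a logical stratifier is used directly as the strata", {
  set.seed(46)
  df <- tibble::tibble(
    group = rep(c("a", "b"), 100),
    basal_dependent = rep(c(TRUE, FALSE), each = 100),
    response = rnorm(200) - ifelse(group == "a", 0.8, 0)
  )
  got <- stratified_group_comparison(df, group, basal_dependent, response)
  expect_equal(nrow(got$bins), 2)
  expect_lt(got$max_adjusted_p, 0.01)
})

test_that("stimulus/response terms are partitioned by name and tested one-sided", {
  set.seed(48)
  nes <- tibble::tibble(
    term = c(sprintf("response to cytokine %d", 1:200),
             sprintf("Cellular STIMULUS pathway %d", 1:50),
             sprintf("metabolic process %d", 1:800)),
    timepoint = "6h",
    nes = c(rnorm(250, -1, 0.5), rnorm(800, 0, 0.5))
  )
  got <- compare_stimulus_term_nes(nes)
  expect_equal(got$n_stimulus, 250)
  expect_equal(got$n_other, 800)
  expect_lt(got$p, 0.001)

  null_terms <- dplyr::mutate(nes, nes = rnorm(1050))
  got_null <- compare_stimulus_term_nes(null_terms)
  expect_gt(got_null$p, 1e-4)

  expect_error(
    compare_stimulus_term_nes(tibble::tibble(term = "metabolism", timepoint = "1h", nes = 1)),
    "partitions"
  )
})
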