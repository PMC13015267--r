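# Orchestration: run configuration with every analysis threshold as an
# explicit, validated default, and the end-to-end pipeline over the
# synthetic study (simulate -> annotate -> differential -> ML -> tau ->
# linking), writing each stage's outputs before the next begins.

RUN_CONFIG_DEFAULTS <- list(
  seed = 1L,
  stages = c("simulate", "annotate", "differential", "ml", "tau", "link"),
  mean_threshold = 10,
  accessibility_fdr = 0.05,
  accessibility_lfc = 1,
  expression_fdr = 0.05,
  expression_lfc = log2(1.5),
  invariant_fdr = 0.2,
  invariant_max_change = 0.2,
  tau_threshold = 0.8,
  ridge_alpha = 1.0,
  ridge_iterations = 10L,
  ridge_subsample = 0.7,
  permutation_repeats = 10L,
  ml_mode = "enhancer",
  n_top_features = 15L,
  synthetic = list()
)

#' Build a validated run configuration
#'
#' All analysis thresholds are explicit named defaults: vehicle mean-count
#' filter 10; accessibility calls at FDR < 0.05 with |log2FC| > 1;
#' expression calls at FDR < 0.05 with |log2FC| >= log2(1.5); invariant
#' genes at FDR > 0.2 with < 20% change; tau restriction at 0.8; ridge
#' alpha 1.0 over 10 x 70% bootstrap subsets; 10 permutation repeats.
#' Unknown keys are rejected by name.
#'
#' @param ... Overrides for any default (see [RUN_CONFIG_DEFAULTS] source
#'   for the full key list); `synthetic` is a list of overrides passed to
#'   [synthetic_config()].
#' @return A `bafdep_run_config` list.
#' @export
run_config <- function(...) {
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(RUN_CONFIG_DEFAULTS, overrides)
  if (!cfg$ml_mode %in% c("all", "enhancer")) {
    abort("ml_mode must be 'all' or 'enhancer'")
  }
  bad_stage <- setdiff(cfg$stages, RUN_CONFIG_DEFAULTS$stages)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  structure(cfg, class = "bafdep_run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are [run_config()] arguments.
#' @return A validated `bafdep_run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

write_stage <- function(obj, path) {
  if (is.matrix(obj)) {
    write_count_matrix(obj, path)
  } else {
    readr::write_tsv(tibble::as_tibble(obj), path, progress = FALSE)
  }
  path
}

#' Run the full synthetic BAF-dependence analysis
#'
#' Executes the stages in dependency order on a seeded synthetic dataset:
#' simulate (peaks, ChIP sets, counts, expression, tissue atlas), annotate
#' (cRE classes + super-enhancer flags), differential (expression test ->
#' invariant genes -> promoter size factors -> accessibility test + calls),
#' ml (binary feature matrix, balanced RF with grid search, MDI +
#' permutation importances, bootstrapped ridge), tau (tissue specificity +
#' restriction enrichment of top accessibility-loss features), and link
#' (PCHi-C matched/mismatched enrichment and per-gene aggregation). Each
#' stage's outputs are written to `outdir` before the next stage begins;
#' identical config and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, a run report: resolved config, per-stage output files
#'   with MD5 checksums, collected warnings, and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("bafdep_run_")) {
  stopifnot(inherits(config, "bafdep_run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  scfg <- do.call(synthetic_config, c(list(seed = config$seed), config$synthetic))
  files <- character()
  warnings <- character()
  results <- list()
  report_path <- file.path(outdir, "run_report.yaml")
  stage <- "simulate"

  emit_report <- function(status) {
    report <- list(
      status = status,
      failed_stage = if (status == "failed") stage else NULL,
      config = unclass(config),
      files = lapply(files, function(f) unname(tools::md5sum(f))),
      warnings = as.list(warnings)
    )
    names(report$files) <- basename(files)
    yaml::write_yaml(report, report_path)
  }

  run <- function() {
    # --- simulate -----------------------------------------------------
    sim <- simulate_perturbation_dataset(scfg)
    gene_universe <- union(sim$annotation$genes$name,
                           sprintf("G%05d", seq_len(scfg$n_genes)))
    gene_universe <- union(gene_universe, feature_names(scfg))
    expr <- simulate_expression_tables(
      scfg,
      gene_names = gene_universe,
      restricted_genes = sim$informative_features
    )
    if ("simulate" %in% config$stages) {
      write_simulation(sim, file.path(outdir, "simulated"))
      files <<- c(files,
                  write_stage(expr$counts, file.path(outdir, "rna_counts.tsv")),
                  write_stage(expr$truth, file.path(outdir, "rna_truth.tsv")))
    }
    results$sim <<- sim
    results$expr <<- expr

    # --- annotate -----------------------------------------------------
    stage <<- "annotate"
    annotation <- annotate_cres(
      sim$peaks,
      c(sim$annotation["genes"], sim$annotation[c(
        "h3k4me3", "h3k4me1", "h3k27ac", "h3k27me3", "ctcf"
      )], list(super_enhancers = sim$annotation$super_enhancers))
    )
    files <<- c(files, write_stage(annotation, file.path(outdir, "cre_annotation.tsv")))
    results$annotation <<- annotation

    # --- differential -------------------------------------------------
    stage <<- "differential"
    rna_diff <- test_differential_counts(expr$counts, expr$design) |>
      call_significant(fdr = config$expression_fdr,
                       lfc_threshold = config$expression_lfc,
                       mode = "expression")
    invariant <- select_invariant_genes(
      rna_diff, config$invariant_fdr, config$invariant_max_change
    )
    prom_map <- annotation$name[annotation$cre_class == "promoter"]
    tssw <- compute_tss_windows(sim$annotation$genes)
    tss_hits <- intersect_sets(sim$peaks, tssw)
    gene_of_peak <- tss_hits |>
      dplyr::filter(.data$query_name %in% prom_map) |>
      dplyr::distinct(.data$query_name, .keep_all = TRUE)
    invariant_promoters <- gene_of_peak$query_name[
      gene_of_peak$subject_name %in% invariant
    ]
    atac <- filter_low_count_peaks(sim$counts, sim$design, config$mean_threshold)
    sf <- compute_size_factors(atac, invariant_promoters)
    atac_diff <- test_differential_counts(atac, sim$design, sf) |>
      call_significant(fdr = config$accessibility_fdr,
                       lfc_threshold = config$accessibility_lfc,
                       mode = "accessibility")
    files <<- c(
      files,
      write_stage(rna_diff, file.path(outdir, "rna_differential.tsv")),
      write_stage(sf, file.path(outdir, "size_factors.tsv")),
      write_stage(atac_diff, file.path(outdir, "atac_differential.tsv"))
    )
    results$rna_diff <<- rna_diff
    results$size_factors <<- sf
    results$atac_diff <<- atac_diff

    # --- ml -----------------------------------------------------------
    stage <<- "ml"
    chip_all <- c(
      sim$annotation[c("h3k4me3", "h3k4me1", "h3k27ac", "h3k27me3", "ctcf")],
      sim$chip
    )
    fm <- build_feature_matrix(sim$peaks, chip_all)
    keep_rows <- fm$peak %in% atac_diff$feature
    diff_by_peak <- atac_diff[match(fm$peak, atac_diff$feature), ]
    if (config$ml_mode == "enhancer") {
      tss_proximal <- fm$peak %in% tss_hits$query_name
      keep_rows <- keep_rows & !tss_proximal & fm$h3k4me3 == 0 & fm$ctcf == 0
      fm <- dplyr::select(fm, -"h3k4me3", -"ctcf")
    }
    fm_used <- fm[keep_rows, , drop = FALSE]
    labels <- diff_by_peak$call[keep_rows] == "down"
    response <- diff_by_peak$log2fc[keep_rows]
    splits <- balance_and_split(labels, seed = config$seed)
    rf <- train_rf(fm_used, labels, splits, seed = config$seed)
    importances <- compute_importances(
      rf, fm_used, labels,
      n_repeats = config$permutation_repeats, seed = config$seed
    )
    ridge <- fit_ridge_bootstrap(
      fm_used, response,
      alpha = config$ridge_alpha, n_iter = config$ridge_iterations,
      subsample_fraction = config$ridge_subsample, seed = config$seed,
      n_top = config$n_top_features
    )
    importance_tbl <- dplyr::left_join(
      importances,
      dplyr::rename(ridge$coefficients, ridge_beta = "beta", ridge_rank = "rank"),
      by = "feature"
    )
    metrics <- list(
      accuracy = rf$metrics$accuracy, auroc = rf$metrics$auroc,
      tpr = rf$metrics$tpr, fpr = rf$metrics$fpr,
      tp = rf$metrics$tp, tn = rf$metrics$tn,
      fp = rf$metrics$fp, fn = rf$metrics$fn,
      best_params = as.list(rf$best_params)
    )
    jsonlite::write_json(metrics, file.path(outdir, "ml_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    files <<- c(
      files, file.path(outdir, "ml_metrics.json"),
      write_stage(importance_tbl, file.path(outdir, "feature_importance.tsv"))
    )
    results$feature_matrix <<- fm_used
    results$ml_labels <<- labels
    results$ml_response <<- response
    results$rf <<- rf
    results$importances <<- importance_tbl
    results$ridge <<- ridge

    # --- tau ----------------------------------------------------------
    stage <<- "tau"
    tau_tbl <- compute_tau(expr$tissue_tpm, threshold = config$tau_threshold)
    loss_features <- ridge$bottom_features
    other_features <- setdiff(ridge$coefficients$feature, loss_features)
    tau_enrichment <- test_restriction_enrichment(
      loss_features, other_features, tau_tbl, config$tau_threshold
    )
    files <<- c(
      files,
      write_stage(tau_tbl, file.path(outdir, "tau.tsv")),
      write_stage(tau_enrichment, file.path(outdir, "tau_enrichment.tsv"))
    )
    results$tau <<- tau_tbl
    results$tau_enrichment <<- tau_enrichment

    # --- link ---------------------------------------------------------
    stage <<- "link"
    pl <- simulate_pchic_links(scfg, genes = gene_universe, cres = sim$peaks)
    gene_sets <- split(pl$genes$name[pl$genes$inducible],
                       pl$genes$stimulus[pl$genes$inducible])
    cre_sets <- split(pl$cres$name[pl$cres$inducible],
                      pl$cres$stimulus[pl$cres$inducible])
    enrichment <- link_enrichment_pairs(pl$links, gene_sets, cre_sets)
    agg <- aggregate_gene_effect_and_correlate(
      pl$links,
      tibble::tibble(cre = pl$cres$name, delta = pl$cres$delta),
      tibble::tibble(gene = pl$genes$name, delta = pl$genes$delta)
    )
    files <<- c(
      files,
      write_stage(pl$links, file.path(outdir, "pchic_links.tsv")),
      write_stage(enrichment, file.path(outdir, "link_enrichment.tsv")),
      write_stage(agg$gene_effects, file.path(outdir, "gene_cre_effects.tsv")),
      write_stage(agg$correlation, file.path(outdir, "gene_cre_correlation.tsv"))
    )
    results$links <<- pl
    results$link_enrichment <<- enrichment
    results$gene_cre <<- agg
  }

  status <- "ok"
  tryCatch(
    withCallingHandlers(
      run(),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        warnings <<- c(warnings, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    ),
    error = function(e) {
      status <<- "failed"
      emit_report("failed")
      abort(paste0("pipeline failed at stage '", stage, "': ",
                   conditionMessage(e)))
    }
  )
  emit_report("ok")
  invisible(list(
    status = status, outdir = outdir, config = config,
    files = files, warnings = warnings, results = results
  ))
}
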