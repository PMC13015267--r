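# Seeded synthetic-data generator with planted ground truth.
#
# The generator emulates the statistical structure of an acute BAF-inhibition
# experiment: widespread, heterogeneous accessibility loss whose per-peak
# magnitude is driven by (i) the peak's cRE class and (ii) planted binary
# memberships in a set of "informative" TF features, observed through
# negative-binomial ATAC counts with per-sample depth factors. Everything is
# keyed to one seed and every record has a ground-truth entry, so each
# downstream stage can be validated exactly.

CRE_CLASSES <- c(
  "promoter", "active_enhancer", "primed_enhancer", "poised_enhancer",
  "ctcf_bound", "unclassified"
)
ENHANCER_CLASSES <- c("active_enhancer", "primed_enhancer", "poised_enhancer")

#' Configuration for the synthetic BAF-inhibition study
#'
#' Defaults define the simulated study conditions: a 5,000-peak genome on
#' four 10-Mb chromosomes, 55 TF ChIP features of which 5 drive accessibility
#' loss at -1 log2FC each, cRE class effects with primed enhancers losing the
#' most accessibility (-2) and promoters/CTCF none, NB counts with dispersion
#' 0.1 (variance = mu + phi * mu^2) at a baseline mean of 200, and three
#' replicates per condition.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_peaks Number of non-overlapping ATAC peaks.
#' @param peak_width Peak width in bp.
#' @param n_features Number of TF ChIP features in the model matrix.
#' @param n_informative_features How many features drive accessibility loss.
#' @param feature_membership_prob Bernoulli probability a peak carries a
#'   feature (informative features are restricted to H3K4me1-positive
#'   enhancer classes; decoys bind anywhere).
#' @param effect_per_feature log2FC shift per informative feature carried.
#' @param feature_effects Optional numeric vector (length `n_features`) of
#'   per-feature log2FC effects overriding the informative/decoy pattern;
#'   use a graded vector to emulate the continuum of real TF importances.
#' @param class_probs Named probabilities over cRE classes.
#' @param class_effects Named mean log2FC per cRE class.
#' @param lfc_noise_sd SD of the per-peak Gaussian log2FC noise.
#' @param baseline_mean Median NB mean of vehicle counts.
#' @param baseline_log_sd SD (log2 scale) of per-peak baseline variation.
#' @param dispersion NB dispersion phi; variance = mu + phi * mu^2.
#' @param depth_factors Per-sample depth multipliers (vehicle then treated);
#'   `NULL` draws mild lognormal depth variation (sd 0.1).
#' @param n_replicates Replicates per condition.
#' @param n_genes Genes in the expression tables.
#' @param frac_invariant_genes Fraction of genes with true log2FC exactly 0.
#' @param gene_lfc_sd SD of true log2FC for non-invariant genes.
#' @param n_tissues Tissues in the tissue-by-gene TPM matrix.
#' @param tau_regimes Named probabilities over tissue-specificity regimes
#'   (`uniform`, `single`, `graded`).
#' @param n_links PCHi-C links to draw.
#' @param link_coupling_prob Probability an inducible gene links to an
#'   inducible cRE of the same stimulus.
#' @param link_distance_range Contact distance bounds in bp.
#' @param frac_inducible_genes,frac_inducible_cres Fractions carrying a
#'   stimulus-inducibility flag in the linking simulation.
#' @return A validated `bafdep_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 4L,
                             chrom_length = 1e7,
                             n_peaks = 5000L,
                             peak_width = 400L,
                             n_features = 55L,
                             n_informative_features = 5L,
                             feature_membership_prob = 0.15,
                             effect_per_feature = -1,
                             feature_effects = NULL,
                             class_probs = c(
                               promoter = 0.20, active_enhancer = 0.30,
                               primed_enhancer = 0.20, poised_enhancer = 0.05,
                               ctcf_bound = 0.15, unclassified = 0.10
                             ),
                             class_effects = c(
                               promoter = 0, active_enhancer = -0.5,
                               primed_enhancer = -2, poised_enhancer = -1,
                               ctcf_bound = 0, unclassified = 0
                             ),
                             lfc_noise_sd = 0.2,
                             baseline_mean = 200,
                             baseline_log_sd = 0.4,
                             dispersion = 0.1,
                             depth_factors = NULL,
                             n_replicates = 3L,
                             n_genes = 2000L,
                             frac_invariant_genes = 0.3,
                             gene_lfc_sd = 1,
                             n_tissues = 20L,
                             tau_regimes = c(uniform = 0.4, single = 0.2, graded = 0.4),
                             n_links = 5000L,
                             link_coupling_prob = 0.5,
                             link_distance_range = c(5e3, 1e6),
                             frac_inducible_genes = 0.3,
                             frac_inducible_cres = 0.3) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_peaks = as.integer(n_peaks),
    peak_width = as.integer(peak_width), n_features = as.integer(n_features),
    n_informative_features = as.integer(n_informative_features),
    feature_membership_prob = feature_membership_prob,
    effect_per_feature = effect_per_feature,
    feature_effects = feature_effects,
    class_probs = class_probs, class_effects = class_effects,
    lfc_noise_sd = lfc_noise_sd, baseline_mean = baseline_mean,
    baseline_log_sd = baseline_log_sd, dispersion = dispersion,
    depth_factors = depth_factors, n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    frac_invariant_genes = frac_invariant_genes, gene_lfc_sd = gene_lfc_sd,
    n_tissues = as.integer(n_tissues), tau_regimes = tau_regimes,
    n_links = as.integer(n_links), link_coupling_prob = link_coupling_prob,
    link_distance_range = link_distance_range,
    frac_inducible_genes = frac_inducible_genes,
    frac_inducible_cres = frac_inducible_cres
  )
  class(cfg) <- "bafdep_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  probs <- c(
    cfg$feature_membership_prob, cfg$frac_invariant_genes,
    cfg$link_coupling_prob, cfg$frac_inducible_genes, cfg$frac_inducible_cres
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  if (cfg$n_informative_features > cfg$n_features) {
    abort("n_informative_features must be <= n_features")
  }
  if (!is.null(cfg$feature_effects) &&
      length(cfg$feature_effects) != cfg$n_features) {
    abort("feature_effects must have length n_features")
  }
  if (!setequal(names(cfg$class_probs), CRE_CLASSES) ||
      !setequal(names(cfg$class_effects), CRE_CLASSES)) {
    abort("class_probs and class_effects must name every cRE class")
  }
  if (abs(sum(cfg$class_probs) - 1) > 1e-8) abort("class_probs must sum to 1")
  if (cfg$n_replicates < 2) abort("at least two replicates per condition")
  if (diff(cfg$link_distance_range) <= 0) abort("bad link_distance_range")
  cfg
}

feature_names <- function(cfg) sprintf("TF%03d", seq_len(cfg$n_features))

sim_depth_factors <- function(cfg) {
  n <- 2L * cfg$n_replicates
  if (!is.null(cfg$depth_factors)) {
    d <- rep_len(cfg$depth_factors, n)
  } else {
    d <- 2^rnorm(n, 0, 0.1 / log(2))
  }
  d
}

#' Simulate a complete BAF-inhibition perturbation dataset
#'
#' Places non-overlapping peaks on synthetic chromosomes, assigns each a cRE
#' class and TF feature memberships, computes the planted true log2FC
#' (class effect + sum of informative-feature effects + Gaussian noise), and
#' draws NB counts for vehicle and treated samples. ChIP interval sets are
#' constructed so that a peak overlaps feature f's set if and only if its
#' membership indicator is 1; decoy ChIP intervals are placed only in
#' peak-free gaps. Annotation inputs (genes/TSS, histone marks, CTCF,
#' super-enhancer sets) are emitted decoy-consistently so the planted classes
#' are exactly recoverable.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `peaks`, `chip` (named list of TF interval
#'   tibbles), `annotation` (genes + mark/CTCF/super-enhancer interval sets),
#'   `counts` (integer matrix peaks x samples), `design` (sample sheet),
#'   and `truth` (per-peak class, memberships, true log2FC, SE flag).
#' @export
simulate_perturbation_dataset <- function(config) {
  cfg <- validate_config(config)
  with_seed(derive_seed(cfg$seed, "perturbation"), {
    margin <- 2000L
    per_chrom <- ceiling(cfg$n_peaks / cfg$n_chroms)
    slot <- floor(cfg$chrom_length / per_chrom)
    jitter_room <- slot - cfg$peak_width - 2L * margin
    if (jitter_room < 0) {
      abort("n_peaks cannot be placed without overlap on this genome")
    }

    chrom_of <- sprintf("chr%d", rep(seq_len(cfg$n_chroms), each = per_chrom))[seq_len(cfg$n_peaks)]
    slot_idx <- (rep(seq_len(per_chrom), times = cfg$n_chroms))[seq_len(cfg$n_peaks)]
    slot_start <- (slot_idx - 1L) * slot
    jitter <- floor(runif(cfg$n_peaks, 0, jitter_room + 1))
    start <- slot_start + margin + jitter
    peaks <- genomic_intervals(
      chrom = chrom_of, start = start, end = start + cfg$peak_width,
      name = sprintf("peak_%05d", seq_len(cfg$n_peaks))
    )

    cre_class <- sample(CRE_CLASSES, cfg$n_peaks, replace = TRUE,
                        prob = cfg$class_probs[CRE_CLASSES])

    feats <- feature_names(cfg)
    effects <- if (is.null(cfg$feature_effects)) {
      c(rep(cfg$effect_per_feature, cfg$n_informative_features),
        rep(0, cfg$n_features - cfg$n_informative_features))
    } else {
      as.numeric(cfg$feature_effects)
    }
    names(effects) <- feats
    informative <- feats[effects != 0]
    membership <- matrix(
      rbinom(cfg$n_peaks * cfg$n_features, 1, cfg$feature_membership_prob),
      nrow = cfg$n_peaks, dimnames = list(peaks$name, feats)
    )
    # Effect-carrying TFs bind only H3K4me1-positive enhancer classes,
    # mirroring lineage TFs concentrated at enhancers; decoys bind anywhere.
    enh <- cre_class %in% ENHANCER_CLASSES
    membership[, informative] <- membership[, informative] * enh

    true_lfc <- unname(cfg$class_effects[cre_class]) +
      as.numeric(membership %*% effects) +
      rnorm(cfg$n_peaks, 0, cfg$lfc_noise_sd)

    # TF ChIP sets: one interval inside each member peak; decoys in gaps.
    gap_anchor <- slot_start + 200L # inside the slot, never inside a peak
    chip <- lapply(seq_along(feats), function(f) {
      member <- which(membership[, f] == 1)
      ivs <- tibble::tibble(
        chrom = peaks$chrom[member],
        start = peaks$start[member] + 50L,
        end = peaks$start[member] + 250L,
        name = sprintf("%s_pk_%05d", feats[f], member)
      )
      decoy_at <- which(membership[, f] == 0 & runif(cfg$n_peaks) < 0.05)
      if (length(decoy_at) > 0) {
        ivs <- dplyr::bind_rows(ivs, tibble::tibble(
          chrom = peaks$chrom[decoy_at],
          start = gap_anchor[decoy_at],
          end = gap_anchor[decoy_at] + 200L,
          name = sprintf("%s_decoy_%05d", feats[f], decoy_at)
        ))
      }
      validate_intervals(ivs)
    })
    names(chip) <- feats

    # Annotation inputs consistent with the planted classes.
    mark_for <- function(classes, tag) {
      idx <- which(cre_class %in% classes)
      validate_intervals(tibble::tibble(
        chrom = peaks$chrom[idx], start = peaks$start[idx],
        end = peaks$end[idx], name = sprintf("%s_%05d", tag, idx)
      ))
    }
    h3k4me1 <- mark_for(ENHANCER_CLASSES, "h3k4me1")
    h3k4me3 <- mark_for("promoter", "h3k4me3")
    h3k27ac <- mark_for("active_enhancer", "h3k27ac")
    h3k27me3 <- mark_for("poised_enhancer", "h3k27me3")
    ctcf <- mark_for("ctcf_bound", "ctcf")

    prom_idx <- which(cre_class == "promoter")
    gene_strand <- rep_len(c("+", "-"), length(prom_idx))
    tss <- peaks$start[prom_idx] + cfg$peak_width %/% 2L
    genes <- tibble::tibble(
      chrom = peaks$chrom[prom_idx],
      start = ifelse(gene_strand == "+", tss, tss - 1199L),
      end = ifelse(gene_strand == "+", tss + 1200L, tss + 1L),
      name = sprintf("G%05d", seq_along(prom_idx)),
      score = 0,
      strand = gene_strand
    )

    active_idx <- which(cre_class == "active_enhancer")
    se_members <- if (length(active_idx) > 0) {
      active_idx[sample.int(length(active_idx),
                            size = max(1, floor(length(active_idx) * 0.2)))]
    } else {
      integer()
    }
    half <- ceiling(length(se_members) / 2)
    se_region <- function(idx) {
      tbl <- tibble::tibble(
        chrom = peaks$chrom[idx],
        start = pmax(0L, peaks$start[idx] - 1000L),
        end = peaks$end[idx] + 1000L,
        name = sprintf("se_%05d", idx)
      )
      if (nrow(tbl) == 0) genomic_intervals(character(), integer(), integer()) else validate_intervals(tbl)
    }
    se_a <- se_region(se_members[seq_len(half)])
    se_b <- se_region(se_members[seq(half + 1, length.out = max(0, length(se_members) - half))])

    depth <- sim_depth_factors(cfg)
    samples <- c(
      sprintf("vehicle_%d", seq_len(cfg$n_replicates)),
      sprintf("treated_%d", seq_len(cfg$n_replicates))
    )
    design <- tibble::tibble(
      sample = samples,
      condition = rep(c("vehicle", "treated"), each = cfg$n_replicates),
      timepoint = 6, dose = 10,
      replicate = rep(seq_len(cfg$n_replicates), 2),
      depth_factor = depth
    )
    base_mu <- cfg$baseline_mean * 2^rnorm(cfg$n_peaks, 0, cfg$baseline_log_sd)
    counts <- matrix(0L, nrow = cfg$n_peaks, ncol = length(samples),
                     dimnames = list(peaks$name, samples))
    for (j in seq_along(samples)) {
      mu_j <- base_mu * depth[j]
      if (design$condition[j] == "treated") mu_j <- mu_j * 2^true_lfc
      counts[, j] <- rnbinom(cfg$n_peaks, mu = mu_j, size = 1 / cfg$dispersion)
    }

    truth <- tibble::tibble(
      name = peaks$name,
      cre_class = cre_class,
      true_log2fc = true_lfc,
      super_enhancer = seq_len(cfg$n_peaks) %in% se_members,
      gene = NA_character_
    )
    truth$gene[prom_idx] <- genes$name
    truth <- dplyr::bind_cols(truth, tibble::as_tibble(membership))

    list(
      peaks = peaks,
      chip = chip,
      annotation = list(
        genes = genes, h3k4me3 = h3k4me3, h3k4me1 = h3k4me1,
        h3k27ac = h3k27ac, h3k27me3 = h3k27me3, ctcf = ctcf,
        super_enhancers = list(se_a, se_b)
      ),
      counts = counts,
      design = design,
      truth = truth,
      informative_features = informative,
      feature_effects = effects,
      config = cfg
    )
  })
}

#' Simulate expression tables for the treatment contrast and tissue atlas
#'
#' Generates gene-level NB counts for a vehicle-vs-treated contrast with a
#' planted fraction of expression-invariant genes (true log2FC exactly 0),
#' plus a tissue-by-gene median-TPM matrix in which each gene follows one of
#' three specificity regimes: `uniform` (identical TPM in every tissue, tau
#' 0), `single` (expressed in exactly one tissue, tau 1), or `graded`
#' (geometric decay across tissues, intermediate tau).
#'
#' @param config A [synthetic_config()].
#' @param gene_names Optional gene identifiers; defaults to
#'   `G00001..G<n_genes>` so they align with the promoter genes emitted by
#'   [simulate_perturbation_dataset()].
#' @param restricted_genes Optional gene names forced into the
#'   single-tissue regime (used to plant tissue-restricted expression for
#'   chosen TF features, emulating lineage factors).
#' @return List with `counts` (genes x samples), `design`, `tissue_tpm`
#'   (tissues x genes matrix), and `truth` (gene, true log2FC, invariant
#'   flag, tau regime).
#' @export
simulate_expression_tables <- function(config, gene_names = NULL,
                                       restricted_genes = character()) {
  cfg <- validate_config(config)
  with_seed(derive_seed(cfg$seed, "expression"), {
    if (is.null(gene_names)) {
      gene_names <- sprintf("G%05d", seq_len(cfg$n_genes))
    }
    n <- length(gene_names)
    invariant <- runif(n) < cfg$frac_invariant_genes
    true_lfc <- ifelse(invariant, 0, rnorm(n, 0, cfg$gene_lfc_sd))

    samples <- c(
      sprintf("vehicle_%d", seq_len(cfg$n_replicates)),
      sprintf("treated_%d", seq_len(cfg$n_replicates))
    )
    design <- tibble::tibble(
      sample = samples,
      condition = rep(c("vehicle", "treated"), each = cfg$n_replicates),
      timepoint = 6, dose = 10,
      replicate = rep(seq_len(cfg$n_replicates), 2)
    )
    base_mu <- cfg$baseline_mean * 2^rnorm(n, 0, cfg$baseline_log_sd)
    counts <- matrix(0L, nrow = n, ncol = length(samples),
                     dimnames = list(gene_names, samples))
    for (j in seq_along(samples)) {
      mu_j <- if (design$condition[j] == "treated") base_mu * 2^true_lfc else base_mu
      counts[, j] <- rnbinom(n, mu = mu_j, size = 1 / cfg$dispersion)
    }

    regime <- sample(names(cfg$tau_regimes), n, replace = TRUE,
                     prob = cfg$tau_regimes)
    regime[gene_names %in% restricted_genes] <- "single"
    tissue_tpm <- matrix(
      0, nrow = cfg$n_tissues, ncol = n,
      dimnames = list(sprintf("tissue_%02d", seq_len(cfg$n_tissues)), gene_names)
    )
    level <- 2^rnorm(n, log2(50), 1)
    for (g in seq_len(n)) {
      tissue_tpm[, g] <- switch(regime[g],
        uniform = rep(level[g], cfg$n_tissues),
        single = {
          v <- numeric(cfg$n_tissues)
          v[sample.int(cfg$n_tissues, 1)] <- level[g]
          v
        },
        graded = level[g] * 0.7^(sample(seq_len(cfg$n_tissues)) - 1)
      )
    }

    list(
      counts = counts,
      design = design,
      tissue_tpm = tissue_tpm,
      truth = tibble::tibble(
        gene = gene_names, true_log2fc = true_lfc,
        invariant = invariant, tau_regime = regime
      )
    )
  })
}

#' Simulate promoter-capture Hi-C links with controllable gene-cRE coupling
#'
#' Draws `n_links` promoter-to-distal-fragment contacts. Genes and cREs are
#' each flagged stimulus-inducible (for one of two stimuli, `stimA`/`stimB`).
#' With probability `link_coupling_prob` a link from an inducible gene is
#' directed to an inducible cRE of the same stimulus ("matched"); otherwise
#' the cRE is drawn uniformly. Matched cREs inherit the gene's planted
#' accessibility delta (plus noise), so per-gene aggregation of linked cRE
#' deltas correlates with the gene's expression delta when coupling is
#' present and not otherwise.
#'
#' @param config A [synthetic_config()].
#' @param genes Character vector of gene names, or a tibble with a `name`
#'   column (optionally `inducible` and `stimulus` to override the planted
#'   flags).
#' @param cres Interval tibble of candidate cREs (distal fragments are the
#'   cRE extended by 500 bp each side), optionally carrying `inducible` and
#'   `stimulus` columns.
#' @return List with `links` (gene, fragment coordinates, distance, cre,
#'   matched flag), `genes` (inducibility + expression delta truth), and
#'   `cres` (inducibility + accessibility delta truth).
#' @export
simulate_pchic_links <- function(config, genes, cres) {
  cfg <- validate_config(config)
  with_seed(derive_seed(cfg$seed, "pchic"), {
    if (is.character(genes)) genes <- tibble::tibble(name = genes)
    genes <- tibble::as_tibble(genes)
    cres <- validate_intervals(cres)
    ng <- nrow(genes)
    nc <- nrow(cres)
    if (ng == 0 || nc == 0) abort("genes and cres must be non-empty")

    if (!"inducible" %in% names(genes)) {
      genes$inducible <- runif(ng) < cfg$frac_inducible_genes
    }
    if (!"stimulus" %in% names(genes)) {
      genes$stimulus <- ifelse(genes$inducible,
                               sample(c("stimA", "stimB"), ng, replace = TRUE),
                               NA_character_)
    }
    if (!"inducible" %in% names(cres)) {
      cres$inducible <- runif(nc) < cfg$frac_inducible_cres
    }
    if (!"stimulus" %in% names(cres)) {
      cres$stimulus <- ifelse(cres$inducible,
                              sample(c("stimA", "stimB"), nc, replace = TRUE),
                              NA_character_)
    }

    genes$delta <- ifelse(genes$inducible, rnorm(ng, -1, 0.6), rnorm(ng, 0, 0.3))
    cres$delta <- ifelse(cres$inducible, rnorm(nc, -0.5, 0.5), rnorm(nc, 0, 0.3))

    gene_idx <- sample.int(ng, cfg$n_links, replace = TRUE)
    matched <- logical(cfg$n_links)
    cre_idx <- integer(cfg$n_links)
    by_stim <- split(seq_len(nc), ifelse(cres$inducible, cres$stimulus, "none"))
    coupled <- runif(cfg$n_links) < cfg$link_coupling_prob
    for (i in seq_len(cfg$n_links)) {
      g <- gene_idx[i]
      pool <- if (isTRUE(genes$inducible[g]) && coupled[i]) {
        by_stim[[genes$stimulus[g]]]
      } else {
        NULL
      }
      if (length(pool) > 0) {
        cre_idx[i] <- if (length(pool) == 1) pool else sample(pool, 1)
        matched[i] <- TRUE
      } else {
        cre_idx[i] <- sample.int(nc, 1)
      }
    }
    # Matched cREs inherit the linked gene's delta (first assignment wins).
    first_match <- !duplicated(cre_idx) & matched
    cres$delta[cre_idx[first_match]] <-
      genes$delta[gene_idx[first_match]] + rnorm(sum(first_match), 0, 0.3)

    dist <- floor(runif(cfg$n_links, cfg$link_distance_range[1],
                        cfg$link_distance_range[2] + 1))
    frag_pad <- 500L
    distal_start <- pmax(0L, cres$start[cre_idx] - frag_pad)
    distal_end <- cres$end[cre_idx] + frag_pad
    prom_width <- 5000L
    prom_end <- distal_start - dist
    prom_start <- prom_end - prom_width
    flip <- prom_start < 0
    prom_start[flip] <- distal_end[flip] + dist[flip]
    prom_end[flip] <- prom_start[flip] + prom_width

    links <- tibble::tibble(
      gene = genes$name[gene_idx],
      chrom = cres$chrom[cre_idx],
      prom_start = as.integer(prom_start),
      prom_end = as.integer(prom_end),
      distal_start = as.integer(distal_start),
      distal_end = as.integer(distal_end),
      distance = as.integer(dist),
      cre = cres$name[cre_idx],
      matched = matched
    )
    list(links = links, genes = genes, cres = cres)
  })
}

#' Write a simulated dataset to disk in pipeline formats
#'
#' Emits the same plain-text formats the analysis consumes: narrowPeak peaks,
#' BED ChIP sets, TSV count matrix/design/truth, and the resolved config as
#' a YAML sidecar.
#'
#' @param sim Output of [simulate_perturbation_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_narrowpeak(sim$peaks, file.path(dir, "peaks.narrowPeak"))
  chip_dir <- file.path(dir, "chip")
  dir.create(chip_dir, showWarnings = FALSE)
  for (f in names(sim$chip)) {
    write_bed(sim$chip[[f]], file.path(chip_dir, paste0(f, ".bed")))
  }
  for (f in c("h3k4me3", "h3k4me1", "h3k27ac", "h3k27me3", "ctcf")) {
    write_bed(sim$annotation[[f]], file.path(dir, paste0(f, ".bed")))
  }
  readr::write_tsv(sim$annotation$genes, file.path(dir, "genes.tsv"), progress = FALSE)
  write_count_matrix(sim$counts, file.path(dir, "atac_counts.tsv"), "peak")
  readr::write_tsv(sim$design, file.path(dir, "design.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  cfg <- sim$config
  cfg$depth_factors <- as.numeric(cfg$depth_factors)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
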