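# Stimulus-response linking: inducible-set definition, PCHi-C gene-cRE link
# enrichment, per-gene aggregation of linked-cRE effects, distance-binned
# comparisons, covariate-stratified group comparisons, and the stimulus-term
# NES test.

#' Define stimulus-inducible sets at two timepoints
#'
#' Members pass `FDR < fdr` and `log2FC >= lfc_threshold` (or
#' `<= -lfc_threshold` for direction `"down"`) at a timepoint; categories
#' `1h_only` / `both` / `6h_only` are assigned by set algebra and are
#' disjoint.
#'
#' @param diff_1h,diff_6h Differential tibbles (`feature`, `log2fc`, `fdr`)
#'   over the same universe.
#' @param fdr FDR cutoff (default 0.05).
#' @param lfc_threshold Fold-change cutoff (default `log2(1.5)`, inclusive).
#' @param direction `"up"` (induced) or `"down"` (repressed).
#' @return Tibble `member`, `direction`, `category`.
#' @export
define_inducible_sets <- function(diff_1h, diff_6h, fdr = 0.05,
                                  lfc_threshold = log2(1.5),
                                  direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!setequal(diff_1h$feature, diff_6h$feature)) {
    n_diff <- length(setdiff(diff_1h$feature, diff_6h$feature)) +
      length(setdiff(diff_6h$feature, diff_1h$feature))
    abort(sprintf(
      "timepoints tested on different universes (symmetric difference: %d features)",
      n_diff
    ))
  }
  members <- function(d) {
    hit <- d$fdr < fdr & if (direction == "up") {
      d$log2fc >= lfc_threshold
    } else {
      d$log2fc <= -lfc_threshold
    }
    d$feature[hit & !is.na(hit)]
  }
  m1 <- members(diff_1h)
  m6 <- members(diff_6h)
  all <- union(m1, m6)
  tibble::tibble(
    member = all,
    direction = direction,
    category = dplyr::case_when(
      all %in% m1 & all %in% m6 ~ "both",
      all %in% m1 ~ "1h_only",
      TRUE ~ "6h_only"
    )
  )
}

#' Enrichment of inducible-gene / inducible-cRE links
#'
#' Counts each link (or, in gene mode, each gene) into a 2x2 table of
#' gene-inducible by cRE-inducible and applies a two-sided Fisher exact
#' test. In gene mode a gene counts as cRE-positive if any linked cRE is
#' inducible. A table with an empty margin has no defined odds ratio and is
#' reported as missing.
#'
#' @param links Link tibble with `gene` and `cre` columns.
#' @param inducible_genes,inducible_cres Character sets.
#' @param unit `"link"` (default) or `"gene"`.
#' @return Tibble with the 2x2 cells, `odds_ratio`, `p`, `note`.
#' @export
test_link_enrichment <- function(links, inducible_genes, inducible_cres,
                                 unit = c("link", "gene")) {
  unit <- match.arg(unit)
  if (nrow(links) == 0) abort("link table is empty")
  if (unit == "link") {
    gx <- links$gene %in% inducible_genes
    cx <- links$cre %in% inducible_cres
  } else {
    per_gene <- links |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(any_cre = any(.data$cre %in% inducible_cres),
                       .groups = "drop")
    gx <- per_gene$gene %in% inducible_genes
    cx <- per_gene$any_cre
  }
  tab <- matrix(
    c(sum(gx & cx), sum(gx & !cx), sum(!gx & cx), sum(!gx & !cx)),
    nrow = 2, byrow = TRUE,
    dimnames = list(gene = c("inducible", "other"),
                    cre = c("inducible", "other"))
  )
  margin_zero <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  res <- if (margin_zero) {
    list(odds_ratio = NA_real_, p = NA_real_)
  } else {
    fisher_or(tab)
  }
  tibble::tibble(
    both = tab[1, 1], gene_only = tab[1, 2],
    cre_only = tab[2, 1], neither = tab[2, 2],
    odds_ratio = res$odds_ratio, p = res$p,
    note = if (margin_zero) "zero margin; odds ratio undefined" else NA_character_
  )
}

#' Link enrichment for matched and mismatched stimulus pairs
#'
#' @param links Link tibble.
#' @param gene_sets,cre_sets Named lists of inducible-gene / inducible-cRE
#'   character sets, one element per stimulus.
#' @param unit Counting unit passed to [test_link_enrichment()].
#' @return Tibble with one row per (gene stimulus, cRE stimulus) pair and a
#'   `matched` flag.
#' @export
link_enrichment_pairs <- function(links, gene_sets, cre_sets,
                                  unit = c("link", "gene")) {
  unit <- match.arg(unit)
  combos <- tidyr::expand_grid(
    gene_stimulus = names(gene_sets), cre_stimulus = names(cre_sets)
  )
  purrr::pmap_dfr(combos, function(gene_stimulus, cre_stimulus) {
    res <- test_link_enrichment(
      links, gene_sets[[gene_stimulus]], cre_sets[[cre_stimulus]], unit = unit
    )
    dplyr::bind_cols(
      tibble::tibble(
        gene_stimulus = gene_stimulus, cre_stimulus = cre_stimulus,
        matched = gene_stimulus == cre_stimulus
      ),
      res
    )
  })
}

#' Per-gene median linked-cRE effect and its correlation with expression
#'
#' Aggregates the accessibility change of all cREs linked to each gene by
#' the median, then reports the Pearson correlation between the per-gene
#' medians and the genes' expression changes. Genes with no linked cRE
#' carrying a delta are excluded with a message.
#'
#' @param links Link tibble with `gene` and `cre`.
#' @param cre_deltas Tibble `cre`, `delta` (accessibility log2FC of the
#'   inhibitor contrast).
#' @param gene_deltas Tibble `gene`, `delta` (expression log2FC of the same
#'   contrast).
#' @return List with `gene_effects` (tibble `gene`, `median_cre_delta`,
#'   `gene_delta`) and `correlation` (tibble `r`, `p`, `n`).
#' @export
aggregate_gene_effect_and_correlate <- function(links, cre_deltas, gene_deltas) {
  joined <- dplyr::inner_join(
    links[, c("gene", "cre")], cre_deltas, by = "cre"
  )
  n_dropped <- length(setdiff(unique(links$gene), unique(joined$gene)))
  if (n_dropped > 0) {
    inform(sprintf("excluded %d gene(s) with no linked cRE delta", n_dropped))
  }
  gene_effects <- joined |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(median_cre_delta = median(.data$delta), .groups = "drop") |>
    dplyr::inner_join(
      dplyr::rename(gene_deltas, gene_delta = "delta"), by = "gene"
    )
  correlation <- if (nrow(gene_effects) >= 3) {
    ct <- cor.test(gene_effects$median_cre_delta, gene_effects$gene_delta,
                   method = "pearson")
    tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                   n = nrow(gene_effects))
  } else {
    tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(gene_effects))
  }
  list(gene_effects = gene_effects, correlation = correlation)
}

decile_bins <- function(x, n_bins = 10L) {
  edges <- quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE, type = 7)
  edges <- unique(edges)
  if (length(edges) < 2) {
    return(rep(1L, length(x)))
  }
  # ties can collapse edges; collapsed (empty) bins are merged rightward
  cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
}

#' Expression change of genes linked to inducible vs other cREs, by distance
#'
#' Links are binned into deciles of contact distance; within each bin the
#' expression fold changes of genes linked to inducible cREs are compared
#' with those linked to non-inducible cREs (two-sided Wilcoxon rank-sum),
#' with BH adjustment across evaluable bins. Bins in which one group is
#' absent are reported with missing statistics and excluded from the BH
#' family.
#'
#' @param links Link tibble with `gene`, `cre`, `distance`.
#' @param gene_fc Tibble `gene`, `log2fc` (expression response to the
#'   stimulus).
#' @param inducible_cres Character set of stimulus-inducible cRE names.
#' @param n_bins Number of distance bins (default 10).
#' @return Tibble per bin: distance range, group sizes, mean fold change and
#'   SEM per group, `p`, `fdr`.
#' @export
distance_binned_effect <- function(links, gene_fc, inducible_cres,
                                   n_bins = 10L) {
  if (nrow(links) < n_bins) abort("fewer links than distance bins")
  d <- dplyr::inner_join(
    links[, c("gene", "cre", "distance")],
    dplyr::rename(gene_fc, gene_log2fc = "log2fc"),
    by = "gene"
  )
  d$bin <- decile_bins(d$distance, n_bins)
  d$inducible <- d$cre %in% inducible_cres
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  out <- d |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      distance_min = min(.data$distance),
      distance_max = max(.data$distance),
      n_inducible = sum(.data$inducible),
      n_other = sum(!.data$inducible),
      mean_fc_inducible = mean(.data$gene_log2fc[.data$inducible]),
      sem_inducible = sem(.data$gene_log2fc[.data$inducible]),
      mean_fc_other = mean(.data$gene_log2fc[!.data$inducible]),
      sem_other = sem(.data$gene_log2fc[!.data$inducible]),
      p = if (sum(.data$inducible) > 0 && sum(!.data$inducible) > 0) {
        suppressWarnings(wilcox.test(
          .data$gene_log2fc[.data$inducible],
          .data$gene_log2fc[!.data$inducible]
        )$p.value)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- p.adjust(out$p[ok], method = "BH")
  out
}

#' Covariate-stratified two-group comparison
#'
#' Controls a group contrast (e.g. primed vs active enhancer accessibility
#' loss) for a numeric covariate (H3K4me1 signal, baseline accessibility,
#' BAF-subunit signal) by binning items into covariate deciles and running a
#' two-sided Wilcoxon rank-sum test within each bin. Bins in which one group
#' is absent are dropped from the family with a message; the Bonferroni
#' factor is the number of evaluable bins and the conservative summary is
#' the maximum corrected p across them. A logical/factor covariate is used
#' directly as the strata (e.g. basal-dependence stratification).
#'
#' @param data A data frame.
#' @param group Column (tidy-eval) with exactly two levels.
#' @param covariate Numeric column (tidy-eval) to stratify on, or a
#'   logical/factor stratifier.
#' @param response Numeric column (tidy-eval) compared between groups.
#' @param n_bins Number of covariate bins (default 10).
#' @return List with `bins` (per-bin tibble: sizes, medians, `p`,
#'   `p_bonferroni`) and `max_adjusted_p`, the summary statistic.
#' @export
stratified_group_comparison <- function(data, group, covariate, response,
                                        n_bins = 10L) {
  df <- tibble::tibble(
    group = dplyr::pull(data, {{ group }}),
    covariate = dplyr::pull(data, {{ covariate }}),
    response = dplyr::pull(data, {{ response }})
  )
  lv <- unique(df$group)
  if (length(lv) != 2) abort("group must have exactly two levels")
  df$bin <- if (is.numeric(df$covariate)) {
    decile_bins(df$covariate, n_bins)
  } else {
    as.integer(factor(df$covariate))
  }
  bins <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_a = sum(.data$group == lv[1]),
      n_b = sum(.data$group == lv[2]),
      median_a = median(.data$response[.data$group == lv[1]]),
      median_b = median(.data$response[.data$group == lv[2]]),
      p = if (sum(.data$group == lv[1]) > 0 && sum(.data$group == lv[2]) > 0) {
        suppressWarnings(wilcox.test(
          .data$response[.data$group == lv[1]],
          .data$response[.data$group == lv[2]]
        )$p.value)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  dropped <- sum(is.na(bins$p))
  if (dropped > 0) {
    inform(sprintf("%d bin(s) lacked one group and were dropped from the family",
                   dropped))
  }
  k <- sum(!is.na(bins$p))
  bins$p_bonferroni <- pmin(1, bins$p * k)
  list(
    bins = bins,
    n_evaluable_bins = k,
    max_adjusted_p = if (k > 0) max(bins$p_bonferroni, na.rm = TRUE) else NA_real_,
    groups = lv
  )
}

#' Are stimulus/response gene-set terms biased toward downregulation?
#'
#' Partitions enrichment terms by a case-insensitive substring match of
#' "stimulus" or "response" in the term name and tests, per timepoint,
#' whether the stimulus/response partition has lower normalized enrichment
#' scores (one-sided Wilcoxon rank-sum).
#'
#' @param nes_table Tibble with `term`, `timepoint`, `nes`.
#' @return Tibble per timepoint: partition sizes and the one-sided `p`.
#' @export
compare_stimulus_term_nes <- function(nes_table) {
  nes_table$is_stimulus <- stringr::str_detect(
    nes_table$term, stringr::regex("stimulus|response", ignore_case = TRUE)
  )
  nes_table |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::group_modify(function(d, key) {
      if (!any(d$is_stimulus) || all(d$is_stimulus)) {
        abort("both term partitions must be non-empty")
      }
      tibble::tibble(
        n_stimulus = sum(d$is_stimulus),
        n_other = sum(!d$is_stimulus),
        p = suppressWarnings(wilcox.test(
          d$nes[d$is_stimulus], d$nes[!d$is_stimulus],
          alternative = "less"
        )$p.value)
      )
    }) |>
    dplyr::ungroup()
}
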