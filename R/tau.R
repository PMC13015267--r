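# Tau tissue-specificity index.
#
# tau = sum_i (1 - x_i / max_i x_i) / (n - 1) over n tissues, computed on
# log2(TPM + 1)-transformed expression. tau = 0 for perfectly uniform
# expression and 1 for expression confined to a single tissue. The
# pseudocount of 1 makes TPM 0 map to a transformed value of 0, which the
# tau = 1 single-tissue limit requires.

#' Tau tissue-specificity index per gene
#'
#' @param tpm Tissue-by-gene matrix of median TPM values (tissues as rows),
#'   or a data frame whose first column holds tissue names.
#' @param pseudocount Added before the log2 transform (default 1).
#' @param threshold Restriction threshold on tau (default 0.8, inclusive).
#' @return Tibble `gene`, `tau`, `restricted`. Genes with zero expression in
#'   every tissue have undefined tau, reported as `NA`.
#' @export
compute_tau <- function(tpm, pseudocount = 1, threshold = 0.8) {
  if (is.data.frame(tpm)) {
    first <- tpm[[1]]
    if (is.character(first) || is.factor(first)) {
      m <- as.matrix(tpm[, -1, drop = FALSE])
      rownames(m) <- as.character(first)
      tpm <- m
    } else {
      tpm <- as.matrix(tpm)
    }
  }
  if (nrow(tpm) < 2) abort("tau requires at least two tissues")
  if (any(tpm < 0)) abort("TPM values must be non-negative")
  x <- log2(tpm + pseudocount)
  n <- nrow(x)
  xmax <- apply(x, 2, max)
  tau <- ifelse(
    xmax > 0,
    colSums(1 - sweep(x, 2, pmax(xmax, .Machine$double.eps), "/")) / (n - 1),
    NA_real_
  )
  tibble::tibble(
    gene = colnames(tpm) %||% sprintf("gene_%04d", seq_along(tau)),
    tau = as.numeric(tau),
    restricted = !is.na(tau) & tau >= threshold
  )
}

#' Odds ratio and Fisher p for a 2x2 table
#'
#' The odds ratio is the cross-product `(a*d)/(b*c)` with a Haldane 0.5
#' correction applied to every cell when any cell is zero; the p-value is
#' the two-sided Fisher exact probability.
#'
#' @param tab 2x2 integer matrix or table.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  list(
    odds_ratio = (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1]),
    p = fisher.test(tab)$p.value
  )
}

#' Enrichment of tissue-restricted expression in a top-feature set
#'
#' Tests whether genes in `top_features` are enriched for tissue-restricted
#' expression (tau at or above the threshold) relative to
#' `comparison_features`, by a two-sided Fisher exact test on the 2x2
#' restricted-by-set table. Features without a tau value are excluded with
#' a message.
#'
#' @param top_features,comparison_features Character vectors of gene names.
#' @param tau_records Tibble from [compute_tau()].
#' @param threshold Restriction threshold (default 0.8).
#' @return Tibble with the table cells, `odds_ratio`, `p`, and the number
#'   of features excluded for lacking tau.
#' @export
test_restriction_enrichment <- function(top_features, comparison_features,
                                        tau_records, threshold = 0.8) {
  if (length(top_features) == 0 || length(comparison_features) == 0) {
    abort("both feature sets must be non-empty")
  }
  lookup <- setNames(tau_records$tau, tau_records$gene)
  sets <- list(top = top_features, comparison = comparison_features)
  n_excluded <- 0L
  counts <- lapply(sets, function(genes) {
    tau <- lookup[genes]
    miss <- is.na(tau)
    n_excluded <<- n_excluded + sum(miss)
    tau <- tau[!miss]
    c(restricted = sum(tau >= threshold), other = sum(tau < threshold))
  })
  if (n_excluded > 0) {
    inform(sprintf("excluded %d feature(s) without a tau value", n_excluded))
  }
  tab <- rbind(top = counts$top, comparison = counts$comparison)
  res <- fisher_or(tab)
  tibble::tibble(
    top_restricted = tab["top", "restricted"],
    top_other = tab["top", "other"],
    comparison_restricted = tab["comparison", "restricted"],
    comparison_other = tab["comparison", "other"],
    odds_ratio = res$odds_ratio,
    p = res$p,
    n_excluded = n_excluded
  )
}
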