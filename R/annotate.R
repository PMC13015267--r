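# cRE classification: TSS proximity plus ChIP-overlap decision tree.
#
# The tree mirrors standard histone-mark logic: TSS-proximal peaks with
# H3K4me3 are promoters; TSS-distal H3K4me1+ peaks are active enhancers if
# H3K27ac is present, poised if H3K27me3 is present (without H3K27ac), and
# primed if neither H3K27 mark is; TSS-distal H3K4me1- peaks with CTCF are
# CTCF-bound; everything else is unclassified. "Overlap" is >= 1 bp with no
# minimum-fraction requirement.

#' 1-kb windows centered on annotated TSSs
#'
#' For `+`-strand genes the TSS is the interval start; for `-`-strand genes
#' it is the last base (`end - 1`). The window is `[TSS - 500, TSS + 500)`,
#' clipped at 0.
#'
#' @param genes Interval tibble of genes with a `strand` column in `{+,-}`.
#' @param half_width Window half-width in bp (default 500).
#' @return Interval tibble of TSS windows, one per gene, named after the
#'   gene.
#' @export
compute_tss_windows <- function(genes, half_width = 500L) {
  genes <- validate_intervals(genes)
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) {
    abort(paste0(
      "gene(s) with unknown strand: ",
      paste(head(genes$name[bad], 5), collapse = ", ")
    ))
  }
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  validate_intervals(tibble::tibble(
    chrom = genes$chrom,
    start = pmax(0L, as.integer(tss) - as.integer(half_width)),
    end = as.integer(tss) + as.integer(half_width),
    name = genes$name,
    score = 0,
    strand = genes$strand
  ))
}

#' Classify ATAC peaks into cRE classes
#'
#' @param peaks Interval tibble of ATAC peaks.
#' @param inputs Named list with `genes` (or precomputed `tss_windows`) and
#'   interval tibbles `h3k4me3`, `h3k4me1`, `h3k27ac`, `h3k27me3`, `ctcf`.
#' @return Tibble with `name`, `cre_class`, and the underlying overlap
#'   indicator columns (`tss_proximal`, one per mark).
#' @export
classify_cres <- function(peaks, inputs) {
  peaks <- validate_intervals(peaks)
  needed <- c("h3k4me3", "h3k4me1", "h3k27ac", "h3k27me3", "ctcf")
  missing <- setdiff(needed, names(inputs))
  if (length(missing) > 0) {
    abort(paste0("annotation inputs lack: ", paste(missing, collapse = ", ")))
  }
  tss_windows <- inputs$tss_windows %||% compute_tss_windows(inputs$genes)

  ov <- tibble::tibble(
    name = peaks$name,
    tss_proximal = overlaps_any(peaks, tss_windows),
    h3k4me3 = overlaps_any(peaks, inputs$h3k4me3),
    h3k4me1 = overlaps_any(peaks, inputs$h3k4me1),
    h3k27ac = overlaps_any(peaks, inputs$h3k27ac),
    h3k27me3 = overlaps_any(peaks, inputs$h3k27me3),
    ctcf = overlaps_any(peaks, inputs$ctcf)
  )
  ov$cre_class <- dplyr::case_when(
    ov$tss_proximal & ov$h3k4me3 ~ "promoter",
    !ov$tss_proximal & ov$h3k4me1 & ov$h3k27ac ~ "active_enhancer",
    !ov$tss_proximal & ov$h3k4me1 & ov$h3k27me3 ~ "poised_enhancer",
    !ov$tss_proximal & ov$h3k4me1 ~ "primed_enhancer",
    !ov$tss_proximal & !ov$h3k4me1 & ov$ctcf ~ "ctcf_bound",
    TRUE ~ "unclassified"
  )
  dplyr::select(ov, "name", "cre_class", dplyr::everything())
}

#' Flag super-enhancer membership
#'
#' An enhancer is flagged if it overlaps the union of the two reference
#' super-enhancer annotation sets.
#'
#' @param enhancers Interval tibble.
#' @param se_sets List of two interval tibbles.
#' @return Tibble with `name` and logical `super_enhancer`.
#' @export
flag_super_enhancers <- function(enhancers, se_sets) {
  if (length(se_sets) != 2) abort("se_sets must contain two interval sets")
  enhancers <- validate_intervals(enhancers)
  flag <- overlaps_any(enhancers, se_sets[[1]]) |
    overlaps_any(enhancers, se_sets[[2]])
  tibble::tibble(name = enhancers$name, super_enhancer = flag)
}

#' Annotate peaks: cRE class plus super-enhancer flag
#'
#' Convenience wrapper combining [classify_cres()] and
#' [flag_super_enhancers()] into the per-peak annotation table the rest of
#' the pipeline consumes.
#'
#' @param peaks Interval tibble of ATAC peaks.
#' @param inputs As for [classify_cres()], optionally with
#'   `super_enhancers` (list of two interval sets).
#' @return Tibble with `name`, `cre_class`, `super_enhancer`.
#' @export
annotate_cres <- function(peaks, inputs) {
  cls <- classify_cres(peaks, inputs)
  out <- dplyr::select(cls, "name", "cre_class")
  if (!is.null(inputs$super_enhancers)) {
    se <- flag_super_enhancers(peaks, inputs$super_enhancers)
    out <- dplyr::left_join(out, se, by = "name")
    out$super_enhancer <- out$super_enhancer & out$cre_class == "active_enhancer"
  } else {
    out$super_enhancer <- FALSE
  }
  out
}
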