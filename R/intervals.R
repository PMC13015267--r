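# Genomic intervals as tibbles.
#
# Coordinates follow the BED convention throughout: 0-based, half-open
# [start, end). Strand is carried but never consulted by overlap arithmetic;
# it matters only when deriving TSS positions (see compute_tss_windows()).

INTERVAL_COLS <- c("chrom", "start", "end", "name", "score", "strand")

#' Construct a tibble of genomic intervals
#'
#' Builds and validates the interval table used across the package:
#' one row per interval, BED-style 0-based half-open coordinates.
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `end > start`.
#' @param name Optional unique identifiers; autogenerated when `NULL`.
#' @param score Optional numeric score (defaults to 0).
#' @param strand One of `"+"`, `"-"`, `"."` per interval (defaults to `"."`).
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @examples
#' genomic_intervals("chr1", c(100, 500), c(200, 900))
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = 0,
                              strand = ".") {
  n <- length(start)
  tbl <- tibble::tibble(
    chrom = as.character(rep_len(chrom, n)),
    start = as.integer(start),
    end = as.integer(end),
    name = if (is.null(name)) sprintf("iv_%05d", seq_len(n)) else as.character(name),
    score = as.numeric(rep_len(score, n)),
    strand = as.character(rep_len(strand, n))
  )
  validate_intervals(tbl)
}

#' Validate an interval tibble
#'
#' Checks the invariants of the interval representation: non-negative starts,
#' `end > start`, strand in `{+, -, .}`, unique names. Returns the input
#' (with any missing optional columns filled) so it can be used in pipes.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @return The validated tibble.
#' @export
validate_intervals <- function(x) {
  x <- tibble::as_tibble(x)
  missing <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(missing) > 0) {
    abort(paste0("interval table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"name" %in% names(x)) x$name <- sprintf("iv_%05d", seq_len(nrow(x)))
  if (!"score" %in% names(x)) x$score <- 0
  if (!"strand" %in% names(x)) x$strand <- "."
  x <- dplyr::select(x, dplyr::all_of(INTERVAL_COLS), dplyr::everything())
  if (any(x$start < 0)) abort("interval starts must be >= 0")
  if (any(x$end <= x$start)) abort("intervals must satisfy end > start")
  if (!all(x$strand %in% c("+", "-", "."))) {
    abort("strand must be one of '+', '-', '.'")
  }
  if (anyDuplicated(x$name)) abort("interval names must be unique within a set")
  x
}

sort_intervals <- function(x) {
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = "*"
  )
}

#' Overlap length of two intervals
#'
#' `max(0, min(end) - max(start))` when the chromosomes match, else 0.
#' Half-open coordinates mean abutting intervals overlap by 0.
#'
#' @param a,b Single-row interval tibbles (or lists with `chrom`, `start`,
#'   `end`).
#' @return Non-negative integer overlap in bp.
#' @examples
#' overlap_length(
#'   genomic_intervals("chr1", 100, 200),
#'   genomic_intervals("chr1", 150, 250)
#' )
#' @export
overlap_length <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) {
    return(0L)
  }
  as.integer(max(0L, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])))
}

#' All overlapping pairs between two interval sets
#'
#' Returns every (query, subject) pair with at least 1 bp of intersection,
#' ordered by query index then subject index.
#'
#' @param query,subject Interval tibbles.
#' @return Tibble with columns `query_index`, `subject_index`, `overlap`
#'   (bp), `query_name`, `subject_name`.
#' @export
intersect_sets <- function(query, subject) {
  query <- validate_intervals(query)
  subject <- validate_intervals(subject)
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble::tibble(
      query_index = integer(), subject_index = integer(), overlap = integer(),
      query_name = character(), subject_name = character()
    ))
  }
  gq <- as_granges(query)
  gs <- as_granges(subject)
  # sets with no chromosome in common are a legitimate (empty) query
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gq, gs, minoverlap = 1L)
  )
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(
    suppressWarnings(GenomicRanges::pintersect(gq[qi], gs[si]))
  )
  ord <- order(qi, si)
  tibble::tibble(
    query_index = qi[ord],
    subject_index = si[ord],
    overlap = as.integer(ov[ord]),
    query_name = query$name[qi[ord]],
    subject_name = subject$name[si[ord]]
  )
}

#' Which peaks overlap any interval of a subject set
#'
#' @param peaks,subject Interval tibbles.
#' @return Logical vector along the rows of `peaks`.
#' @export
overlaps_any <- function(peaks, subject) {
  peaks <- validate_intervals(peaks)
  if (nrow(subject) == 0) {
    return(rep(FALSE, nrow(peaks)))
  }
  hits <- intersect_sets(peaks, subject)
  seq_len(nrow(peaks)) %in% hits$query_index
}

#' Assign each peak the label of its largest-overlap segment
#'
#' Implements largest-overlap assignment against a labeled segmentation
#' (e.g. chromatin states): each peak receives the label of the segment
#' with which it shares the most bp. Ties are broken deterministically in
#' favour of the leftmost (smallest start) segment; peaks overlapping no
#' segment get `"unassigned"`.
#'
#' @param peaks Interval tibble.
#' @param segmentation Interval tibble with a `label` column; segments must
#'   be non-overlapping within each chromosome.
#' @return Tibble with `name` (peak) and `label`.
#' @export
assign_largest_overlap <- function(peaks, segmentation) {
  peaks <- validate_intervals(peaks)
  segmentation <- validate_intervals(segmentation)
  if (!"label" %in% names(segmentation)) {
    abort("segmentation requires a 'label' column")
  }
  seg_hits <- intersect_sets(segmentation, segmentation)
  if (any(seg_hits$query_index != seg_hits$subject_index)) {
    abort("segmentation intervals must be non-overlapping within a chromosome")
  }
  hits <- intersect_sets(peaks, segmentation)
  out <- tibble::tibble(name = peaks$name, label = "unassigned")
  if (nrow(hits) > 0) {
    hits$seg_start <- segmentation$start[hits$subject_index]
    hits$label <- segmentation$label[hits$subject_index]
    best <- hits |>
      dplyr::arrange(
        .data$query_index, dplyr::desc(.data$overlap), .data$seg_start
      ) |>
      dplyr::distinct(.data$query_index, .keep_all = TRUE)
    out$label[best$query_index] <- best$label
  }
  out
}
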