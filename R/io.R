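# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED6, ENCODE narrowPeak (10 columns), and TSV matrices with a header.
# Writers emit sorted, tab-separated, newline-terminated records.

NARROWPEAK_COLS <- c(
  "chrom", "start", "end", "name", "score", "strand",
  "signalValue", "pValue", "qValue", "peak"
)

#' Read a BED3/BED6 file into an interval tibble
#'
#' @param path Path to a headerless BED file (3 or 6 columns).
#' @return Validated interval tibble.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  if (ncol(raw) < 3) abort("BED file must have at least 3 columns")
  names(raw)[1:3] <- c("chrom", "start", "end")
  if (ncol(raw) >= 4) names(raw)[4] <- "name"
  if (ncol(raw) >= 5) names(raw)[5] <- "score"
  if (ncol(raw) >= 6) names(raw)[6] <- "strand"
  validate_intervals(raw[, seq_len(min(ncol(raw), 6))])
}

#' Write intervals as BED6
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- sort_intervals(validate_intervals(x))
  readr::write_tsv(
    x[, INTERVAL_COLS],
    path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' The 10-column narrowPeak layout; the summit offset column (`peak`) is
#' preserved but unused downstream.
#'
#' @param path Path to a narrowPeak file.
#' @return Validated interval tibble with narrowPeak extra columns.
#' @export
read_narrowpeak <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = NARROWPEAK_COLS, show_col_types = FALSE, progress = FALSE,
    comment = "#"
  )
  validate_intervals(raw)
}

#' Write intervals in narrowPeak format
#'
#' Missing narrowPeak columns are filled with the format's conventional
#' placeholders (`signalValue` 0, `pValue`/`qValue` -1, summit -1).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(x, path) {
  x <- validate_intervals(x)
  if (!"signalValue" %in% names(x)) x$signalValue <- 0
  if (!"pValue" %in% names(x)) x$pValue <- -1
  if (!"qValue" %in% names(x)) x$qValue <- -1
  if (!"peak" %in% names(x)) x$peak <- -1L
  x <- sort_intervals(x)
  readr::write_tsv(
    x[, NARROWPEAK_COLS],
    path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a count matrix TSV (features x samples, first column = feature)
#'
#' @param path Path to a TSV with a header row; first column holds feature
#'   names, remaining columns one sample each.
#' @return Integer matrix with feature rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(raw[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(raw[[1]])
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Write a count matrix TSV
#'
#' @param counts Matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param feature_col Name of the first column in the header.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, feature_col = "feature") {
  tbl <- tibble::as_tibble(counts, rownames = feature_col)
  readr::write_tsv(tbl[order(tbl[[feature_col]]), ], path, progress = FALSE)
  invisible(path)
}
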