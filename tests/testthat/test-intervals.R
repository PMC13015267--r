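test_that("overlap_length follows the half-open convention", {
  a <- genomic_intervals("chr1", 100, 200)
  b <- genomic_intervals("chr1", 150, 250)
  expect_identical(overlap_length(a, b), 50L)
  expect_identical(overlap_length(b, a), 50L)

  abut <- genomic_intervals("chr1", 200, 300)
  expect_identical(overlap_length(a, abut), 0L)

  other <- genomic_intervals("chr2", 100, 200)
  expect_identical(overlap_length(a, other), 0L)
})

test_that("overlap_length is symmetric on random interval pairs", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_intervals(1)
    b <- random_intervals(1)
    expect_identical(overlap_length(a, b), overlap_length(b, a))
  }
})

test_that("intersect_sets finds exactly the overlapping pairs", {
  q <- genomic_intervals("chr1", 0, 10, name = "q1")
  s <- genomic_intervals("chr1", c(5, 20), c(8, 30), name = c("s1", "s2"))
  hits <- intersect_sets(q, s)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$overlap, 3L)
  expect_equal(hits$subject_name, "s1")

  disjoint <- intersect_sets(
    genomic_intervals("chr1", 0, 10),
    genomic_intervals("chr1", 100, 110)
  )
  expect_equal(nrow(disjoint), 0)
})

test_that("intersect_sets matches the all-pairs brute force on random sets", {
  set.seed(7)
  for (i in 1:20) {
    q <- random_intervals(sample(1:200, 1))
    s <- random_intervals(sample(1:200, 1))
    got <- intersect_sets(q, s)[, c("query_index", "subject_index", "overlap")]
    want <- bf_intersect(q, s)
    want <- want[order(want$query_index, want$subject_index), ]
    expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
  }
})

test_that("assign_largest_overlap picks the biggest overlap, leftmost on ties", {
  seg <- validate_intervals(tibble::tibble(
    chrom = "chr1", start = c(0, 150), end = c(150, 400),
    name = c("segA", "segB"), label = c("A", "B")
  ))
  # peak [100, 270): 50 bp in A, 120 bp in B
  peak <- genomic_intervals("chr1", 100, 270, name = "p1")
  expect_equal(assign_largest_overlap(peak, seg)$label, "B")

  inside <- genomic_intervals("chr1", 10, 60, name = "p2")
  expect_equal(assign_largest_overlap(inside, seg)$label, "A")

  # peak [90, 210): exactly 60 bp in each -> leftmost segment wins
  tie <- genomic_intervals("chr1", 90, 210, name = "p3")
  expect_equal(assign_largest_overlap(tie, seg)$label, "A")

  nowhere <- genomic_intervals("chr2", 0, 100, name = "p4")
  expect_equal(assign_largest_overlap(nowhere, seg)$label, "unassigned")
})

test_that("assign_largest_overlap is invariant to input ordering", {
  set.seed(11)
  seg <- validate_intervals(tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 10),
    start = rep(seq(0, 900, by = 100), 2),
    end = rep(seq(100, 1000, by = 100), 2),
    name = sprintf("seg%02d", 1:20),
    label = sample(LETTERS[1:4], 20, replace = TRUE)
  ))
  peaks <- random_intervals(50, n_chroms = 2, max_pos = 900)
  ref <- assign_largest_overlap(peaks, seg)
  perm_p <- sample.int(nrow(peaks))
  perm_s <- sample.int(nrow(seg))
  shuffled <- assign_largest_overlap(peaks[perm_p, ], seg[perm_s, ])
  expect_equal(
    shuffled$label[match(ref$name, shuffled$name)],
    ref$label
  )
})

test_that("assign_largest_overlap rejects overlapping segmentations", {
  seg <- validate_intervals(tibble::tibble(
    chrom = "chr1", start = c(0, 50), end = c(100, 150),
    name = c("a", "b"), label = c("A", "B")
  ))
  expect_error(
    assign_largest_overlap(genomic_intervals("chr1", 0, 10), seg),
    "non-overlapping"
  )
})

test_that("interval validation enforces the invariants", {
  expect_error(genomic_intervals("chr1", -5, 10), ">= 0")
  expect_error(genomic_intervals("chr1", 10, 10), "end > start")
  expect_error(genomic_intervals("chr1", 0, 10, strand = "x"), "strand")
  expect_error(
    genomic_intervals("chr1", c(0, 5), c(10, 15), name = c("a", "a")),
    "unique"
  )
})

test_that("BED and narrowPeak files round-trip through the readers", {
  iv <- random_intervals(25, seed = 3)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(iv, bed)
  back <- read_bed(bed)
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  expect_equal(
    as.data.frame(dplyr::arrange(iv[, cols], chrom, start, end)),
    as.data.frame(back[, cols]),
    ignore_attr = TRUE
  )

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  iv$signalValue <- runif(nrow(iv))
  iv$pValue <- -1
  iv$qValue <- -1
  iv$peak <- 5L
  write_narrowpeak(iv, np)
  back_np <- read_narrowpeak(np)
  expect_equal(nrow(back_np), nrow(iv))
  expect_true(all(back_np$peak == 5L))
})

test_that("count matrices round-trip and reject negatives", {
  m <- matrix(5:10, nrow = 3, dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  expect_equal(read_count_matrix(path), m)
})
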