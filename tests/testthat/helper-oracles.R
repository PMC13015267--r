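# Independent brute-force oracles and small fixture builders.

# All-pairs interval intersection, the oracle for intersect_sets():
# every (i, j) combination is scanned with the direct min/max formula.
bf_intersect <- function(query, subject) {
  grid <- expand.grid(i = seq_len(nrow(query)), j = seq_len(nrow(subject)))
  ov <- pmin(query$end[grid$i], subject$end[grid$j]) -
    pmax(query$start[grid$i], subject$start[grid$j])
  keep <- query$chrom[grid$i] == subject$chrom[grid$j] & ov > 0
  tibble::tibble(
    query_index = grid$i[keep],
    subject_index = grid$j[keep],
    overlap = as.integer(ov[keep])
  )
}

# Step-up Benjamini-Hochberg, the oracle for p.adjust(method = "BH").
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Exhaustive two-sided Fisher exact p for a 2x2 table: sum hypergeometric
# probabilities of all tables with the same margins that are no more likely
# than the observed one.
bf_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pairwise Mann-Whitney AUROC (ties count one half).
bf_auroc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

random_intervals <- function(n, n_chroms = 3, max_pos = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  genomic_intervals(
    chrom = sample(sprintf("chr%d", seq_len(n_chroms)), n, replace = TRUE),
    start = start,
    end = start + sample.int(300, n, replace = TRUE),
    name = sprintf("rand_%04d", seq_len(n))
  )
}

# A small, fast synthetic study used across tests.
small_config <- function(seed = 1L, ...) {
  synthetic_config(
    seed = seed, n_peaks = 600L, n_genes = 300L, n_links = 500L,
    n_chroms = 2L, chrom_length = 3e6, ...
  )
}

two_group_design <- function(n_rep = 3) {
  tibble::tibble(
    sample = c(paste0("vehicle_", seq_len(n_rep)), paste0("treated_", seq_len(n_rep))),
    condition = rep(c("vehicle", "treated"), each = n_rep)
  )
}

nb_matrix <- function(n, mu, size, design, seed = 1) {
  set.seed(seed)
  ns <- nrow(design)
  matrix(
    rnbinom(n * ns, mu = mu, size = size), nrow = n,
    dimnames = list(sprintf("f%05d", seq_len(n)), design$sample)
  )
}
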