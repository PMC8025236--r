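# Shared fixture builders for the test suite. Everything is generated in
# code; no files on disk.

# Minimal CtTable with explicit values; one housekeeping assay per sample.
make_ct_table <- function(assay_ct, hk_ct = 20, group = "g") {
  # assay_ct: named list assay -> vector of ct (one per sample/replicate)
  rows <- list()
  n_rep <- length(assay_ct[[1L]])
  for (r in seq_len(n_rep)) {
    sid <- sprintf("s%d", r)
    rows[[length(rows) + 1L]] <- data.frame(
      assay_id = "hk1", sample_id = sid, group = group, replicate = r,
      ct = hk_ct, is_housekeeping = TRUE, stringsAsFactors = FALSE)
    for (a in names(assay_ct)) {
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = a, sample_id = sid, group = group, replicate = r,
        ct = assay_ct[[a]][r], is_housekeeping = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Normalized-expression table straight from delta-Ct values:
# deltas is a list group -> assay -> replicate vector.
make_norm_table <- function(deltas) {
  rows <- list()
  for (g in names(deltas)) {
    for (a in names(deltas[[g]])) {
      v <- deltas[[g]][[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        assay_id = a, sample_id = sprintf("%s_s%d", g, seq_along(v)),
        group = g, replicate = seq_along(v), delta_ct = v,
        rel_expr = 2^(-v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Exhaustive hypergeometric upper tail P(X >= x) by direct summation.
hyper_tail_oracle <- function(x, size_a, size_b, universe) {
  ks <- x:min(size_a, size_b)
  sum(choose(size_a, ks) * choose(universe - size_a, size_b - ks)) /
    choose(universe, size_b)
}

# Exhaustive two-sided Fisher p for a 2x2 with margins (K targets, n in
# bin, N universe) and observed in-bin target count x: sum of all
# hypergeometric point probabilities no larger than the observed one.
fisher_two_sided_oracle <- function(x, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  pk <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  px <- pk[ks == x]
  sum(pk[pk <= px * (1 + 1e-7)])
}

# Hand Pearson chi-square on a 2x2 given as four counts (row-wise).
pearson_oracle <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - E)^2 / E)
}
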