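# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG substream, then restore the caller's
# RNG state. Each generator owns a fixed offset so adding a generator never
# perturbs existing streams; seeds are folded below 2^31.
with_substream <- function(seed, offset, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.double(seed) + offset) %% 2147483647)
  force(expr)
}

.SUBSTREAM <- c(
  derepression = 101, ct = 211, cohort = 307, ld = 401,
  dose = 503, bootstrap = 601
)

stop_if_not_scalar_number <- function(x, name, positive = FALSE,
                                      nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  }
  invisible(x)
}

# Zero-padded gene/assay/sample identifier vectors.
make_ids <- function(prefix, n) {
  sprintf("%s%0*d", prefix, max(4L, nchar(as.character(n))), seq_len(n))
}

# Pearson chi-square on a 2x2 table without continuity correction; returns
# statistic and p (df = 1). Used where the classical uncorrected form is the
# documented statistic.
pearson_chisq_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)))
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       expected = E)
}
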