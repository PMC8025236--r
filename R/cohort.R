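# Cohort stratification: Ward clustering of standardized miRNA-signature
# expression and cluster-by-annotation contingency analysis.

#' Standardize a cohort expression matrix
#'
#' Scales each feature (column) to mean 0 and sample standard deviation 1.
#' Zero-variance features cannot be standardized and are dropped with a
#' warning; an optional `log2(x + 1)` transform for read-count-scale data is
#' applied first.
#'
#' @param m Numeric matrix, samples in rows, features in columns.
#' @param log_transform Apply `log2(x + 1)` before standardizing (for
#'   reads-per-million-scale matrices). Default `FALSE`.
#' @return The standardized matrix; dropped feature names in
#'   `attr(, "dropped_features")`.
#' @export
standardize_matrix <- function(m, log_transform = FALSE) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  if (log_transform) m <- log2(m + 1)
  v <- apply(m, 2L, stats::var)
  zero <- v <= 0 | !is.finite(v)
  if (all(zero)) stop("all features have zero variance", call. = FALSE)
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s", sum(zero),
                    paste(utils::head(colnames(m)[zero], 5L), collapse = ", ")),
            call. = FALSE)
  }
  out <- scale(m[, !zero, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped_features") <- colnames(m)[zero]
  out
}

#' Ward hierarchical clustering of cohort samples
#'
#' Agglomerative clustering of samples with Ward's minimum-variance
#' criterion (squared Euclidean distances in the Lance-Williams update,
#' i.e. `hclust(method = "ward.D2")` on Euclidean distances), cut to exactly
#' `k` clusters. Deterministic for a given matrix.
#'
#' @param m Numeric matrix, samples in rows (typically from
#'   [standardize_matrix()]).
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @return Object of class `ward_clust`: `cluster` (named integer vector of
#'   labels 1..k), `k`, and the `hclust` merge tree in `tree`.
#' @export
#' @examples
#' sim <- simulate_cohort(n_samples = 30, n_clusters = 2, separation = 10,
#'                        seed = 1)
#' cl <- ward_cluster(standardize_matrix(sim$matrix), k = 2)
#' table(cl$cluster, sim$truth$cluster_labels)
ward_cluster <- function(m, k) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
  cl <- stats::cutree(tree, k = k)
  if (is.null(names(cl))) names(cl) <- rownames(m)
  structure(list(cluster = cl, k = as.integer(k), tree = tree),
            class = "ward_clust")
}

#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf("Ward clustering: %d samples in %d clusters\n",
              length(x$cluster), x$k))
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Suggest a cluster number by average silhouette width
#'
#' Scores candidate `k` values by the mean silhouette width of the Ward
#' partition and reports the best. Advisory only: the stratification
#' functions never pick `k` automatically.
#'
#' @param m Numeric matrix, samples in rows.
#' @param k_range Candidate cluster counts.
#' @return Named numeric vector of mean silhouette widths, with the
#'   suggested `k` in `attr(, "suggested_k")`.
#' @export
suggest_k <- function(m, k_range = 2:6) {
  m <- as.matrix(m)
  d <- as.matrix(stats::dist(m))
  widths <- vapply(k_range, function(k) {
    cl <- ward_cluster(m, k)$cluster
    mean(vapply(seq_along(cl), function(i) {
      own <- cl == cl[i]; own[i] <- FALSE
      a <- if (any(own)) mean(d[i, own]) else 0
      b <- min(vapply(setdiff(unique(cl), cl[i]),
                      function(g) mean(d[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1)))
  }, numeric(1))
  names(widths) <- as.character(k_range)
  attr(widths, "suggested_k") <- k_range[which.max(widths)]
  widths
}

#' Cluster-by-annotation contingency analysis
#'
#' Cross-tabulates cluster assignment against a categorical annotation,
#' computes the global Pearson chi-square (no continuity correction,
#' `df = (r-1)(c-1)`), and flags per-cell enrichment or depletion from
#' standardized (adjusted) residuals
#' `(O - E) / sqrt(E (1 - row margin)(1 - column margin))` at |z| > 1.96.
#'
#' @param assign A `ward_clust` object or a named vector of cluster labels.
#' @param annotation Categorical label per sample: either a named vector or
#'   a data frame with columns `sample_id` and `category`.
#' @return Object of class `contingency_report`: `table` (cluster x
#'   category counts), `statistic`, `df`, `p_value`, `stdres`, and `flags`
#'   (`"enriched"`, `"depleted"` or `""` per cell).
#' @export
cluster_annotation_enrichment <- function(assign, annotation) {
  cl <- if (inherits(assign, "ward_clust")) assign$cluster else assign
  if (is.data.frame(annotation)) {
    stopifnot(all(c("sample_id", "category") %in% names(annotation)))
    ann <- stats::setNames(annotation$category, annotation$sample_id)
  } else ann <- annotation
  if (!is.null(names(cl)) && !is.null(names(ann))) {
    missing_ann <- setdiff(names(cl), names(ann))
    if (length(missing_ann)) {
      stop("unannotated sample(s): ",
           paste(utils::head(missing_ann, 5L), collapse = ", "), call. = FALSE)
    }
    ann <- ann[names(cl)]
  }
  if (length(ann) != length(cl)) {
    stop("annotation length does not match assignment", call. = FALSE)
  }
  if (length(unique(ann)) < 2L) {
    stop("annotation needs at least two categories", call. = FALSE)
  }
  tab <- table(cluster = cl, category = ann)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    bad <- c(rownames(tab)[rowSums(tab) == 0], colnames(tab)[colSums(tab) == 0])
    stop("empty margin(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  flags <- matrix("", nrow = nrow(tab), ncol = ncol(tab),
                  dimnames = dimnames(tab))
  flags[ct$stdres > 1.96] <- "enriched"
  flags[ct$stdres < -1.96] <- "depleted"
  structure(list(
    table = tab, statistic = unname(ct$statistic),
    df = unname(ct$parameter), p_value = ct$p.value,
    stdres = ct$stdres, flags = flags
  ), class = "contingency_report")
}

#' @export
print.contingency_report <- function(x, ...) {
  cat(sprintf("Cluster x annotation contingency: chi-square = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  cat("Flags (|standardized residual| > 1.96):\n")
  print(x$flags, quote = FALSE)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions (up to label renaming), ~0 for independent
#' ones. Used to score recovery of planted cluster structure.
#'
#' @param a,b Label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}
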