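# Detection of de-repressed direct miRNA targets from fold-change profiles:
# global shift statistics, ranked equal-count binning, per-bin enrichment,
# bin selection, cross-experiment consensus and target intersection.
#
# This is the package's core inference. Transcriptional effects of miRNA
# loss are typically too mild for fold-change cutoffs, so genes are ranked,
# split into equal-count bins, and predicted-target enrichment is measured
# per bin; consistently enriched bins across experiments are intersected and
# crossed with the prediction annotation to nominate direct targets.

check_profile <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("gene_id", "log2fc") %in% names(profile))) {
    stop("a fold-change profile needs columns `gene_id` and `log2fc`",
         call. = FALSE)
  }
  if (anyDuplicated(profile$gene_id)) {
    stop("duplicate gene_id in profile", call. = FALSE)
  }
  if (any(!is.finite(profile$log2fc))) {
    stop("log2fc must be finite for every gene", call. = FALSE)
  }
  invisible(profile)
}

target_ids_of <- function(annot) {
  stopifnot(all(c("gene_id", "is_predicted_target") %in% names(annot)))
  annot$gene_id[annot$is_predicted_target]
}

#' Build a target annotation from context scores
#'
#' Marks genes as predicted miRNA targets when their context score is
#' strictly below `threshold` (more negative = stronger predicted
#' repression). Genes with no score are non-targets.
#'
#' @param gene_id Character vector of gene identifiers (the universe).
#' @param context_score Numeric vector (NA for unscored genes).
#' @param threshold Context-score cutoff, default -0.15.
#' @return TargetAnnotation data frame with `gene_id`, `context_score`,
#'   `is_predicted_target`; the threshold is kept in
#'   `attr(, "cs_threshold")`.
#' @export
target_annotation <- function(gene_id, context_score, threshold = -0.15) {
  stopifnot(length(gene_id) == length(context_score))
  if (anyDuplicated(gene_id)) stop("duplicate gene_id", call. = FALSE)
  out <- data.frame(
    gene_id = as.character(gene_id), context_score = context_score,
    is_predicted_target = !is.na(context_score) & context_score < threshold,
    stringsAsFactors = FALSE
  )
  attr(out, "cs_threshold") <- threshold
  out
}

#' Global de-repression shift of predicted targets
#'
#' The primary summary of a fold-change profile: the median log2 fold-change
#' of predicted targets minus that of all other genes, with a seeded
#' bootstrap SEM of the median difference and a two-sided Wilcoxon
#' (Mann-Whitney) rank-sum p-value comparing the two distributions.
#'
#' @param profile Fold-change profile data frame (`gene_id`, `log2fc`).
#' @param annot TargetAnnotation over the same universe.
#' @param n_bootstrap Bootstrap replicates for the SEM (0 skips the
#'   bootstrap, returning `NA` SEM).
#' @param seed Seed for the bootstrap resampling.
#' @return Object of class `shift_result` with `median_shift`, `sem`,
#'   `wilcoxon_p`, and group sizes.
#' @export
#' @examples
#' sim <- simulate_derepression_profiles(
#'   synthetic_config(n_genes = 2000, n_targets = 200, seed = 5))
#' global_shift(sim$profiles[[1]], sim$annotation, n_bootstrap = 100)
global_shift <- function(profile, annot, n_bootstrap = 1000L, seed = 1L) {
  check_profile(profile)
  targets <- target_ids_of(annot)
  is_t <- profile$gene_id %in% targets
  x <- profile$log2fc[is_t]          # targets
  y <- profile$log2fc[!is_t]         # others
  if (length(x) < 2L) stop("need at least 2 target genes", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 non-target genes", call. = FALSE)
  shift <- stats::median(x) - stats::median(y)
  sem <- NA_real_
  if (n_bootstrap > 0L) {
    boots <- with_substream(seed, .SUBSTREAM[["bootstrap"]], {
      vapply(seq_len(n_bootstrap), function(i) {
        stats::median(sample(x, replace = TRUE)) -
          stats::median(sample(y, replace = TRUE))
      }, numeric(1))
    })
    sem <- stats::sd(boots)
  }
  # normal approximation: exact enumeration is infeasible (and tied) at
  # transcriptome scale
  p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
  structure(list(
    median_shift = shift, sem = sem, wilcoxon_p = p,
    n_targets = length(x), n_others = length(y)
  ), class = "shift_result")
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    "Target de-repression: median log2FC shift %+.4f %s (targets n = %d vs others n = %d)\n",
    x$median_shift,
    if (is.na(x$sem)) "" else sprintf("± %.4f SEM", x$sem),
    x$n_targets, x$n_others))
  cat(sprintf("  Wilcoxon rank-sum p = %.3g\n", x$wilcoxon_p))
  invisible(x)
}

#' Rank genes and split into equal-count bins
#'
#' Sorts genes by log2 fold-change, descending — bin 1 holds the most
#' up-regulated genes — with fold-change ties broken by lexicographic
#' `gene_id` so the partition is deterministic. Bin sizes are
#' `floor(N / n_bins)` with the remainder distributed one gene each to the
#' lowest-index bins; the partition is exact and total.
#'
#' @param profile Fold-change profile data frame.
#' @param n_bins Number of bins (default 10).
#' @return Object of class `bin_assignment`: a named integer vector mapping
#'   `gene_id` to bin index, with `n_bins` and the bin sizes as attributes.
#' @export
#' @examples
#' p <- data.frame(gene_id = letters[1:10], log2fc = 10:1 / 10)
#' table(rank_and_bin(p, n_bins = 5))
rank_and_bin <- function(profile, n_bins = 10L) {
  check_profile(profile)
  n <- nrow(profile)
  n_bins <- as.integer(n_bins)
  if (n < n_bins) stop("fewer genes than bins", call. = FALSE)
  ord <- order(-profile$log2fc, profile$gene_id)
  base <- n %/% n_bins
  sizes <- rep.int(base, n_bins) + c(rep.int(1L, n %% n_bins),
                                     rep.int(0L, n_bins - n %% n_bins))
  bins <- rep.int(seq_len(n_bins), times = sizes)
  out <- integer(n)
  out[ord] <- bins
  names(out) <- profile$gene_id
  structure(out, n_bins = as.integer(n_bins), bin_sizes = sizes,
            class = "bin_assignment")
}

#' Per-bin enrichment of predicted targets
#'
#' For each bin, compares the observed number of predicted targets with the
#' expectation under uniform allocation (`gene_count * total_targets / N`),
#' reporting `log2(observed / expected)` (a 0.5 pseudo-count is added to
#' both terms only when a bin holds zero targets, keeping the ratio finite)
#' and a contingency p-value from the 2x2 table (in-bin vs rest) x (target
#' vs non-target): Pearson chi-square without continuity correction, or
#' Fisher's exact test whenever any expected cell is below 5.
#'
#' @param bins A `bin_assignment` from [rank_and_bin()].
#' @param annot TargetAnnotation over the same gene universe.
#' @return Object of class `bin_enrichment`: a data frame with one row per
#'   bin (`bin`, `gene_count`, `observed_targets`, `expected_targets`,
#'   `log2_obs_exp`, `p_value`, `test`).
#' @export
bin_enrichment <- function(bins, annot) {
  stopifnot(inherits(bins, "bin_assignment"))
  universe <- names(bins)
  if (!setequal(universe, annot$gene_id)) {
    stop("bin assignment and annotation universes differ", call. = FALSE)
  }
  targets <- target_ids_of(annot)
  n_targets <- length(targets)
  if (n_targets == 0L) stop("no predicted targets in universe", call. = FALSE)
  n <- length(bins)
  n_bins <- attr(bins, "n_bins")
  is_t <- universe %in% targets

  rows <- lapply(seq_len(n_bins), function(b) {
    in_bin <- unname(bins) == b
    size <- sum(in_bin)
    obs <- sum(in_bin & is_t)
    expd <- size * n_targets / n
    eps <- if (obs == 0L) 0.5 else 0
    tab <- matrix(c(obs, size - obs,
                    n_targets - obs, n - size - (n_targets - obs)),
                  nrow = 2L, byrow = TRUE)
    expected_cells <- outer(rowSums(tab), colSums(tab)) / n
    if (any(expected_cells < 5)) {
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher"
    } else {
      p <- pearson_chisq_2x2(tab)$p_value
      test <- "chisq"
    }
    data.frame(
      bin = b, gene_count = size, observed_targets = obs,
      expected_targets = expd,
      log2_obs_exp = log2((obs + eps) / (expd + eps)),
      p_value = p, test = test, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("bin_enrichment", class(out))
  out
}

#' @export
print.bin_enrichment <- function(x, ...) {
  cat(sprintf("Target enrichment across %d ranked bins (%d genes, %d targets)\n",
              nrow(x), sum(x$gene_count), sum(x$observed_targets)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Select enriched top bins and depleted bottom bins
#'
#' `"fixed"` applies the canonical split for a 10-bin ranking: bins 1-4 as
#' the up-regulated (target-enriched) selection and bins 7-10 as the
#' down-regulated (target-depleted) one. `"adaptive"` instead takes the
#' maximal prefix of bins with `log2_obs_exp > 0` and `p < 0.05`, and the
#' maximal suffix with `log2_obs_exp < 0` and `p < 0.05`.
#'
#' @param table A `bin_enrichment` table.
#' @param mode `"fixed"` or `"adaptive"`.
#' @param alpha Per-bin significance threshold for adaptive mode.
#' @return List with integer vectors `top_bins` and `bottom_bins` (either
#'   may be empty in adaptive mode, with a warning).
#' @export
select_bins <- function(table, mode = c("fixed", "adaptive"), alpha = 0.05) {
  mode <- match.arg(mode)
  n_bins <- nrow(table)
  if (mode == "fixed") {
    if (n_bins != 10L) {
      stop("fixed bin selection requires exactly 10 bins", call. = FALSE)
    }
    return(list(top_bins = 1:4, bottom_bins = 7:10))
  }
  enr <- table$log2_obs_exp > 0 & table$p_value < alpha
  dep <- table$log2_obs_exp < 0 & table$p_value < alpha
  top <- if (enr[1L]) seq_len(which.min(c(enr, FALSE)) - 1L) else integer(0)
  bottom <- if (dep[n_bins]) {
    rev_dep <- rev(dep)
    (n_bins - (which.min(c(rev_dep, FALSE)) - 1L) + 1L):n_bins
  } else integer(0)
  if (!length(top) && !length(bottom)) {
    warning("no bins met the adaptive selection criteria", call. = FALSE)
  }
  list(top_bins = top, bottom_bins = bottom)
}

#' Cross-experiment consensus of regulated genes
#'
#' Intersects, across all experiments, the genes falling in each
#' experiment's selected top bins (commonly up-regulated genes) and bottom
#' bins (commonly down-regulated genes). Pairwise overlap significance
#' between experiments is assessed with the one-sided Fisher's exact test.
#'
#' @param assignments List of `bin_assignment` objects over an identical
#'   gene universe (>= 2 experiments).
#' @param selections A single selection list (from [select_bins()]) applied
#'   to all experiments, or a list of per-experiment selections.
#' @return Object of class `consensus_sets` with `up_genes`, `down_genes`,
#'   per-experiment selected-set sizes, and the pairwise Fisher p-values.
#' @export
consensus_sets <- function(assignments, selections) {
  if (length(assignments) < 2L) {
    stop("need at least 2 experiments", call. = FALSE)
  }
  universe <- names(assignments[[1L]])
  for (a in assignments[-1L]) {
    if (!setequal(names(a), universe)) {
      d <- length(union(setdiff(names(a), universe),
                        setdiff(universe, names(a))))
      stop(sprintf("experiments have mismatched universes (symmetric difference %d genes)", d),
           call. = FALSE)
    }
  }
  if (!is.null(selections$top_bins)) {
    selections <- rep(list(selections), length(assignments))
  }
  stopifnot(length(selections) == length(assignments))
  top_sets <- Map(function(a, s) names(a)[unname(a) %in% s$top_bins],
                  assignments, selections)
  bottom_sets <- Map(function(a, s) names(a)[unname(a) %in% s$bottom_bins],
                     assignments, selections)
  pairwise_p <- function(sets) {
    idx <- utils::combn(length(sets), 2L)
    apply(idx, 2L, function(ij) {
      overlap_test(sets[[ij[1L]]], sets[[ij[2L]]], universe)$p_value
    })
  }
  up <- Reduce(intersect, top_sets)
  down <- Reduce(intersect, bottom_sets)
  structure(list(
    up_genes = sort(up), down_genes = sort(down),
    universe = universe,
    selected_sizes = data.frame(
      experiment = seq_along(assignments),
      n_top = lengths(top_sets), n_bottom = lengths(bottom_sets)
    ),
    pairwise_fisher_p = list(
      top = if (all(lengths(top_sets) > 0)) pairwise_p(top_sets) else numeric(0),
      bottom = if (all(lengths(bottom_sets) > 0)) pairwise_p(bottom_sets) else numeric(0)
    )
  ), class = "consensus_sets")
}

#' @export
print.consensus_sets <- function(x, ...) {
  cat(sprintf("Consensus regulated genes over %d experiments:\n",
              nrow(x$selected_sizes)))
  cat(sprintf("  commonly up-regulated:   %d genes\n", length(x$up_genes)))
  cat(sprintf("  commonly down-regulated: %d genes\n", length(x$down_genes)))
  invisible(x)
}

#' High-confidence direct targets from consensus and prediction
#'
#' Intersects the consensus up-regulated genes with the predicted-target
#' annotation: genes both consistently induced upon miRNA loss and
#' predicted as targets. Association between target status and
#' consensus-up membership over the whole universe is tested by Pearson
#' chi-square (df = 1, no continuity correction) on the 2x2 table.
#'
#' @param consensus A `consensus_sets` object.
#' @param annot TargetAnnotation over the same universe.
#' @return Object of class `direct_targets`: `genes`, the 2x2 `table`,
#'   `chisq`, `p_value` (both `NA` with `undefined = TRUE` when the
#'   consensus up-set is empty).
#' @export
direct_targets <- function(consensus, annot) {
  stopifnot(inherits(consensus, "consensus_sets"))
  universe <- consensus$universe
  if (!setequal(universe, annot$gene_id)) {
    stop("consensus and annotation universes differ", call. = FALSE)
  }
  targets <- target_ids_of(annot)
  if (!length(intersect(targets, universe))) {
    stop("no predicted targets in the universe", call. = FALSE)
  }
  up <- consensus$up_genes
  genes <- sort(intersect(up, targets))
  if (length(up) == 0L) {
    return(structure(list(genes = character(0), table = NULL,
                          chisq = NA_real_, p_value = NA_real_,
                          undefined = TRUE), class = "direct_targets"))
  }
  n <- length(universe)
  k <- length(genes)
  tab <- matrix(c(k, length(targets) - k,
                  length(up) - k, n - length(targets) - length(up) + k),
                nrow = 2L, byrow = TRUE,
                dimnames = list(target = c("yes", "no"),
                                consensus_up = c("yes", "no")))
  chi <- pearson_chisq_2x2(tab)
  structure(list(genes = genes, table = tab, chisq = chi$statistic,
                 p_value = chi$p_value, undefined = FALSE),
            class = "direct_targets")
}

#' @export
print.direct_targets <- function(x, ...) {
  cat(sprintf("Direct-target set: %d genes\n", length(x$genes)))
  if (!x$undefined) {
    cat(sprintf("  target status x consensus-up: chi-square = %.2f, p = %.3g\n",
                x$chisq, x$p_value))
  } else {
    cat("  association undefined (empty consensus up-set)\n")
  }
  invisible(x)
}

#' One-call de-repression analysis over several experiments
#'
#' Convenience wrapper: ranks and bins each profile, scores per-bin target
#' enrichment, selects bins, intersects across experiments and nominates
#' direct targets.
#'
#' @param profiles List of fold-change profile data frames over a common
#'   universe.
#' @param annot TargetAnnotation.
#' @param n_bins Number of ranking bins.
#' @param mode Bin-selection mode, see [select_bins()].
#' @return List with `bins` (assignments), `enrichment` (tables),
#'   `selection`, `consensus` and `direct` components.
#' @export
derepression_analysis <- function(profiles, annot, n_bins = 10L,
                                  mode = c("fixed", "adaptive")) {
  mode <- match.arg(mode)
  assignments <- lapply(profiles, rank_and_bin, n_bins = n_bins)
  enrichment <- lapply(assignments, bin_enrichment, annot = annot)
  selections <- lapply(enrichment, select_bins, mode = mode)
  consensus <- consensus_sets(assignments, selections)
  list(bins = assignments, enrichment = enrichment,
       selection = selections, consensus = consensus,
       direct = direct_targets(consensus, annot))
}
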