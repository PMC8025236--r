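# Ct-level qPCR miRNA analysis: detection filtering, housekeeping-median
# delta-Ct normalization, differential calling and overlap testing.

#' Filter a Ct table to detected measurements
#'
#' Keeps only rows whose Ct is present and strictly below the detection
#' ceiling; an assay retained in neither measurement row of the table is
#' dropped entirely. The ids of dropped assays are attached as an attribute
#' and reported via a message.
#'
#' @param ct A CtTable data frame (`assay_id`, `sample_id`, `group`,
#'   `replicate`, `ct`, `is_housekeeping`).
#' @param detection_ceiling Ct at or above which a measurement is treated as
#'   undetected (default 28; a raw Ct of exactly 28 is excluded).
#' @return The filtered CtTable; `attr(, "dropped_assays")` lists assays with
#'   no surviving measurement. An all-filtered input yields an empty table
#'   with a warning, not an error.
#' @export
#' @examples
#' ct <- data.frame(assay_id = "a", sample_id = c("s1", "s2", "s3"),
#'                  group = "g", replicate = 1:3, ct = c(25.1, 29.3, NA),
#'                  is_housekeeping = FALSE)
#' filter_detected(ct)$ct
filter_detected <- function(ct, detection_ceiling = 28) {
  check_ct_table(ct)
  keep <- !is.na(ct$ct) & ct$ct < detection_ceiling
  out <- ct[keep, , drop = FALSE]
  dropped <- setdiff(unique(ct$assay_id), unique(out$assay_id))
  if (length(dropped)) {
    message(sprintf("filter_detected: dropped %d assay(s) with no detected measurement",
                    length(dropped)))
  }
  if (nrow(out) == 0L) {
    warning("all measurements removed by detection filter", call. = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "dropped_assays") <- dropped
  out
}

check_ct_table <- function(ct) {
  needed <- c("assay_id", "sample_id", "group", "replicate", "ct",
              "is_housekeeping")
  missing <- setdiff(needed, names(ct))
  if (length(missing)) {
    stop("CtTable is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 45)
  if (any(bad)) {
    stop("Ct values must be missing or in (0, 45]; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(ct$assay_id, ct$sample_id, ct$replicate)
  if (anyDuplicated(key)) {
    stop("(assay, sample, replicate) combinations must be unique",
         call. = FALSE)
  }
  invisible(ct)
}

#' Normalize Ct values over the housekeeping median
#'
#' Per sample, `delta_ct = ct - median(housekeeping Cts of that sample)` and
#' relative expression is `2^(-delta_ct)`, the standard comparative-Ct
#' quantification. Housekeeping rows themselves are not returned.
#'
#' @param ct A (typically detection-filtered) CtTable.
#' @return A NormalizedExpressionTable data frame (`assay_id`, `sample_id`,
#'   `group`, `replicate`, `delta_ct`, `rel_expr`).
#' @export
#' @examples
#' ct <- data.frame(assay_id = c("hk1", "a"), sample_id = "s1", group = "g",
#'                  replicate = 1L, ct = c(20, 24),
#'                  is_housekeeping = c(TRUE, FALSE))
#' normalize_expression(ct)   # delta_ct 4, rel_expr 1/16
normalize_expression <- function(ct) {
  check_ct_table(ct)
  hk <- ct[ct$is_housekeeping & !is.na(ct$ct), , drop = FALSE]
  hk_median <- tapply(hk$ct, hk$sample_id, stats::median)
  target <- ct[!ct$is_housekeeping, , drop = FALSE]
  no_hk <- setdiff(unique(target$sample_id), names(hk_median))
  if (length(no_hk)) {
    stop("no detected housekeeping assay for sample(s): ",
         paste(no_hk, collapse = ", "), call. = FALSE)
  }
  delta <- target$ct - unname(hk_median[target$sample_id])
  out <- data.frame(
    assay_id = target$assay_id, sample_id = target$sample_id,
    group = target$group, replicate = target$replicate,
    delta_ct = delta, rel_expr = 2^(-delta), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Call differentially expressed miRNAs between two groups
#'
#' Per assay, the log2 fold-change of group A over group B is
#' `mean(delta_ct in B) - mean(delta_ct in A)` (a lower delta-Ct means higher
#' expression, so one cycle equals one log2 unit), with a two-sided Welch
#' t-test on the per-replicate delta-Ct values. Membership in the regulated
#' set requires strictly `|log2fc| > fc_threshold` and `p < p_threshold` on
#' the raw p-value; an optional Benjamini-Hochberg adjustment can be switched
#' on instead.
#'
#' @param norm A NormalizedExpressionTable from [normalize_expression()].
#' @param group_a,group_b The two group labels compared (fold-change of A
#'   over B).
#' @param fc_threshold Absolute log2 fold-change threshold (strict).
#' @param p_threshold P-value threshold (strict).
#' @param adjust Multiple-testing adjustment applied before thresholding:
#'   `"none"` (default, raw p-values) or `"BH"`.
#' @return An object of class `mirna_diff`: a data frame with one row per
#'   testable assay (`assay_id`, `log2fc`, `p_value`, `direction`,
#'   `regulated`) and the thresholds and test recorded as attributes. Assays
#'   with fewer than two detected replicates in either group are skipped with
#'   a warning; assays detected in only one group are excluded rather than
#'   imputed.
#' @export
differential_mirnas <- function(norm, group_a, group_b, fc_threshold = 0.5,
                                p_threshold = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("assay_id", "group", "delta_ct") %in% names(norm)))
  norm <- norm[norm$group %in% c(group_a, group_b), , drop = FALSE]
  if (nrow(norm) == 0L) stop("no rows for the requested groups", call. = FALSE)
  skipped <- character(0)
  rows <- lapply(split(norm, norm$assay_id), function(d) {
    a <- d$delta_ct[d$group == group_a]
    b <- d$delta_ct[d$group == group_b]
    if (length(a) < 2L || length(b) < 2L) {
      skipped <<- c(skipped, d$assay_id[1L])
      return(NULL)
    }
    tt <- stats::t.test(a, b)   # Welch, two-sided
    data.frame(
      assay_id = d$assay_id[1L],
      log2fc = mean(b) - mean(a),
      p_value = tt$p.value, stringsAsFactors = FALSE
    )
  })
  if (length(skipped)) {
    warning(sprintf("skipped %d assay(s) with <2 replicates in a group: %s",
                    length(skipped),
                    paste(utils::head(skipped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(assay_id = character(0),
                                      log2fc = numeric(0),
                                      p_value = numeric(0))
  rownames(res) <- NULL
  p_used <- if (adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  res$direction <- ifelse(res$log2fc > 0, "up", "down")
  res$regulated <- abs(res$log2fc) > fc_threshold & p_used < p_threshold
  attr(res, "fc_threshold") <- fc_threshold
  attr(res, "p_threshold") <- p_threshold
  attr(res, "test") <- "Welch two-sided t-test on delta-Ct replicates"
  attr(res, "adjust") <- adjust
  attr(res, "groups") <- c(a = group_a, b = group_b)
  class(res) <- c("mirna_diff", class(res))
  res
}

#' @export
print.mirna_diff <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("Differential miRNA calling: %s vs %s\n", g[["a"]], g[["b"]]))
  cat(sprintf("  %d assays tested, %d regulated (|log2FC| > %s, p < %s, %s)\n",
              nrow(x), sum(x$regulated), format(attr(x, "fc_threshold")),
              format(attr(x, "p_threshold")),
              if (attr(x, "adjust") == "none") "raw p" else "BH-adjusted p"))
  print.data.frame(utils::head(x[order(x$p_value), ], 10L))
  invisible(x)
}

#' Fisher's exact overlap test for two identifier sets
#'
#' Tests whether the overlap between two sets drawn from a common universe
#' exceeds the hypergeometric expectation, using the one-sided (enrichment)
#' Fisher's exact test on the 2x2 membership table.
#'
#' @param set_a,set_b Character vectors of identifiers, subsets of
#'   `universe`.
#' @param universe Character vector: the common identifier universe.
#' @return Object of class `overlap_test`: overlap count, set sizes,
#'   universe size, expected overlap and the enrichment p-value.
#' @export
#' @examples
#' u <- as.character(1:100)
#' overlap_test(u[1:10], u[6:15], u)
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("both sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  tab <- matrix(c(
    k, length(set_a) - k,
    length(set_b) - k, length(universe) - length(set_a) - length(set_b) + k
  ), nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  structure(list(
    overlap_count = k,
    set_sizes = c(a = length(set_a), b = length(set_b)),
    universe_size = length(universe),
    expected_overlap = length(set_a) * length(set_b) / length(universe),
    p_value = p
  ), class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Set overlap: %d (sets %d and %d in universe %d; expected %.2f)\n",
    x$overlap_count, x$set_sizes[["a"]], x$set_sizes[["b"]],
    x$universe_size, x$expected_overlap))
  cat(sprintf("  Fisher's exact (enrichment) p = %.3g\n", x$p_value))
  invisible(x)
}

#' Composite dilution factor of a serial-dilution protocol
#'
#' The final dilution factor of a protocol is the product of its step
#' factors; e.g. a 1:4 post-preamplification dilution followed by a 1:20 PCR
#' dilution gives a final factor of 80.
#'
#' @param steps Numeric vector of per-step dilution factors (each >= 1; pass
#'   4 for a 1:4 step).
#' @return The composite factor (1 for an empty protocol).
#' @export
#' @examples
#' composite_dilution_factor(c(4, 20))   # 80
#' composite_dilution_factor(c(4, 50))   # 200
composite_dilution_factor <- function(steps) {
  if (length(steps) == 0L) return(1)
  if (any(!is.finite(steps)) || any(steps < 1)) {
    stop("each dilution step must be a finite factor >= 1", call. = FALSE)
  }
  prod(steps)
}

#' miRNA loading percentage from an RNA immunoprecipitation
#'
#' The fraction of total miRNA copies recovered in an immunoprecipitate,
#' given that the input lane assayed only `input_fraction` of the total:
#' `rip_copies / (input_copies / input_fraction) * 100`.
#'
#' @param rip_copies Copies measured in the IP (>= 0).
#' @param input_copies Copies measured in the input aliquot (> 0).
#' @param input_fraction Fraction of total lysate used as input (default
#'   0.05, i.e. 5\% input).
#' @return Loading percentage.
#' @export
#' @examples
#' rip_loading_fraction(200, 100)   # 10 percent
rip_loading_fraction <- function(rip_copies, input_copies,
                                 input_fraction = 0.05) {
  stop_if_not_scalar_number(rip_copies, "rip_copies", nonneg = TRUE)
  stop_if_not_scalar_number(input_copies, "input_copies", positive = TRUE)
  if (input_fraction <= 0 || input_fraction > 1) {
    stop("input_fraction must be in (0, 1]", call. = FALSE)
  }
  rip_copies / (input_copies / input_fraction) * 100
}
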