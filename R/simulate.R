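#' Synthetic-data configuration
#'
#' Bundles the knobs shared by the synthetic generators: the size of the gene
#' universe, the number of predicted miRNA targets planted inside it, the
#' de-repression shift those targets carry, the spread of the log2
#' fold-change background, and the qPCR noise model (housekeeping Ct level,
#' technical replicate noise, detection ceiling). Defaults mirror a
#' high-throughput TaqMan screen over ~11,000 expressed genes with 945
#' predicted targets carrying a subtle +0.10 log2 median shift.
#'
#' @param n_genes Number of genes in the expression universe.
#' @param n_targets Number of planted predicted-target genes
#'   (`n_targets <= n_genes`).
#' @param target_shift Median log2 fold-change added to target genes
#'   (log2 units).
#' @param background_sd Standard deviation of the null log2 fold-change
#'   background (log2 units, > 0).
#' @param n_experiments Number of independent fold-change profiles generated
#'   over the same gene universe.
#' @param ct_mean_hk Mean cycle threshold of housekeeping assays (cycles).
#' @param ct_tech_sd Technical replicate noise on Ct values (cycles, >= 0).
#' @param detection_ceiling Ct above which an assay is considered
#'   undetected (cycles).
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#'
#' @return An object of class `synthetic_config` (a named list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 200, n_targets = 20, seed = 1)
#' cfg$target_shift
synthetic_config <- function(n_genes = 11000L, n_targets = 945L,
                             target_shift = 0.10, background_sd = 0.5,
                             n_experiments = 4L, ct_mean_hk = 20,
                             ct_tech_sd = 0.25, detection_ceiling = 28,
                             seed = 1L) {
  stop_if_not_scalar_number(n_genes, "n_genes", positive = TRUE)
  stop_if_not_scalar_number(n_targets, "n_targets", nonneg = TRUE)
  stop_if_not_scalar_number(background_sd, "background_sd", positive = TRUE)
  stop_if_not_scalar_number(ct_tech_sd, "ct_tech_sd", nonneg = TRUE)
  stop_if_not_scalar_number(target_shift, "target_shift")
  stop_if_not_scalar_number(seed, "seed")
  if (n_targets > n_genes) {
    stop("invalid config: n_targets exceeds n_genes", call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_targets = as.integer(n_targets),
    target_shift = target_shift, background_sd = background_sd,
    n_experiments = as.integer(n_experiments), ct_mean_hk = ct_mean_hk,
    ct_tech_sd = ct_tech_sd, detection_ceiling = detection_ceiling,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Simulate fold-change profiles with planted de-repressed targets
#'
#' Generates `n_experiments` per-gene log2 fold-change profiles over a common
#' gene universe. Non-target genes are drawn from a zero-median Normal
#' background; a planted subset of predicted targets is drawn from the same
#' distribution shifted by `target_shift`, emulating the subtle global
#' de-repression seen when a repressing miRNA is lost. Each planted target is
#' assigned a TargetScan-style context score drawn uniformly in
#' [-0.60, -0.15), i.e. below the prediction threshold.
#'
#' @param config A [synthetic_config()].
#' @return A list with components:
#'   \item{profiles}{named list of data frames (`gene_id`, `log2fc`), one per
#'     experiment.}
#'   \item{annotation}{target annotation data frame (`gene_id`,
#'     `context_score`, `is_predicted_target`), threshold in
#'     `attr(, "cs_threshold")`.}
#'   \item{truth}{planted truth: target ids and the true shift.}
#' @export
#' @examples
#' sim <- simulate_derepression_profiles(
#'   synthetic_config(n_genes = 500, n_targets = 50, seed = 3))
#' length(sim$profiles)
simulate_derepression_profiles <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_substream(config$seed, .SUBSTREAM[["derepression"]], {
    genes <- make_ids("g", config$n_genes)
    target_ids <- sort(sample(genes, config$n_targets))
    is_target <- genes %in% target_ids
    profiles <- lapply(seq_len(config$n_experiments), function(i) {
      fc <- stats::rnorm(config$n_genes, mean = 0, sd = config$background_sd)
      fc[is_target] <- fc[is_target] + config$target_shift
      data.frame(gene_id = genes, log2fc = fc, stringsAsFactors = FALSE)
    })
    names(profiles) <- sprintf("experiment_%d", seq_along(profiles))
    cs <- rep(NA_real_, config$n_genes)
    cs[is_target] <- stats::runif(config$n_targets, min = -0.60, max = -0.15)
    annotation <- data.frame(
      gene_id = genes, context_score = cs,
      is_predicted_target = is_target, stringsAsFactors = FALSE
    )
    attr(annotation, "cs_threshold") <- -0.15
    list(
      profiles = profiles,
      annotation = annotation,
      truth = list(target_gene_ids = target_ids,
                   true_shift = config$target_shift)
    )
  })
}

#' Simulate a qPCR Ct experiment with planted regulated assays
#'
#' Builds a long-format cycle-threshold table for a two-group comparison:
#' housekeeping assays centred at `ct_mean_hk`, non-regulated assays with a
#' common mean in both groups, and `n_regulated` assays whose Ct differs by
#' `regulated_shift` cycles between groups (a 1-cycle delta-delta-Ct equals a
#' 2-fold expression change). Technical noise is Normal with sd `ct_tech_sd`.
#' A `dropout_fraction` of the non-housekeeping assays is pushed above the
#' detection ceiling so downstream detection filtering has work to do.
#'
#' @param config A [synthetic_config()].
#' @param n_assays Number of non-housekeeping miRNA assays.
#' @param n_regulated Number of planted differentially expressed assays
#'   (`<= n_assays`).
#' @param regulated_shift Between-group Ct difference of regulated assays
#'   (cycles); the planted |log2 fold-change| equals this value.
#' @param groups Character vector of exactly two group labels.
#' @param n_replicates Samples (replicates) per group, >= 2.
#' @param n_housekeeping Number of housekeeping assays.
#' @param dropout_fraction Fraction of miRNA assays pushed above the
#'   detection ceiling in all samples.
#' @return A list with `ct` (a CtTable data frame with columns `assay_id`,
#'   `sample_id`, `group`, `replicate`, `ct`, `is_housekeeping`) and `truth`
#'   (regulated assay ids, their planted log2 fold-changes, dropped assay
#'   ids).
#' @export
simulate_ct_experiment <- function(config = synthetic_config(),
                                   n_assays = 40L, n_regulated = 5L,
                                   regulated_shift = 1.0,
                                   groups = c("stem", "non_stem"),
                                   n_replicates = 3L,
                                   n_housekeeping = 3L,
                                   dropout_fraction = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  if (length(groups) != 2L || anyDuplicated(groups)) {
    stop("`groups` must be exactly two distinct labels", call. = FALSE)
  }
  if (n_regulated > n_assays) {
    stop("n_regulated must not exceed n_assays", call. = FALSE)
  }
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  stop_if_not_scalar_number(dropout_fraction, "dropout_fraction", nonneg = TRUE)

  with_substream(config$seed, .SUBSTREAM[["ct"]], {
    assays <- make_ids("mir", n_assays)
    hk <- make_ids("hk", n_housekeeping)
    regulated <- if (n_regulated > 0L) sort(sample(assays, n_regulated)) else character(0)
    n_drop <- round(dropout_fraction * n_assays)
    dropped <- if (n_drop > 0L) sort(sample(assays, n_drop)) else character(0)

    # Baseline assay means sit comfortably inside the detection window.
    base_mean <- stats::setNames(
      stats::runif(n_assays, min = 21, max = 25.5), assays)
    shift_sign <- stats::setNames(
      sample(c(-1, 1), n_regulated, replace = TRUE), regulated)

    grid <- expand.grid(
      assay_id = c(hk, assays), group = groups,
      replicate = seq_len(n_replicates),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$sample_id <- sprintf("%s_s%d", grid$group, grid$replicate)
    grid$is_housekeeping <- grid$assay_id %in% hk

    mu <- ifelse(grid$is_housekeeping, config$ct_mean_hk,
                 base_mean[grid$assay_id])
    reg_row <- grid$assay_id %in% regulated & grid$group == groups[2L]
    if (any(reg_row)) {
      mu[reg_row] <- mu[reg_row] +
        regulated_shift * shift_sign[grid$assay_id[reg_row]]
    }
    ct <- mu + stats::rnorm(nrow(grid), sd = config$ct_tech_sd)
    ct[grid$assay_id %in% dropped] <-
      config$detection_ceiling + 2 + abs(stats::rnorm(sum(grid$assay_id %in% dropped)))

    ct_table <- data.frame(
      assay_id = grid$assay_id, sample_id = grid$sample_id,
      group = grid$group, replicate = grid$replicate, ct = ct,
      is_housekeeping = grid$is_housekeeping, stringsAsFactors = FALSE
    )
    # log2FC of group A over B: a +shift in group B's Ct means higher
    # expression in B is *lower*; sign bookkeeping follows delta-Ct algebra.
    truth_fc <- stats::setNames(regulated_shift * shift_sign, regulated)
    list(ct = ct_table,
         truth = list(regulated_assays = regulated,
                      planted_log2fc = truth_fc,
                      dropped_assays = dropped))
  })
}

#' Simulate a clustered tumor cohort with a linked annotation
#'
#' Draws a samples-by-features expression matrix whose rows fall into
#' `n_clusters` groups with cluster-specific feature means separated by
#' `separation` standardized units, plus one categorical annotation that
#' matches the true cluster label with probability `annotation_association`
#' (and is uniform over categories otherwise).
#'
#' @param n_samples,n_features Matrix dimensions.
#' @param n_clusters Number of planted clusters (>= 2).
#' @param separation Distance between adjacent cluster means in units of the
#'   within-cluster standard deviation.
#' @param annotation_association Probability that a sample's annotation
#'   equals its true cluster's category.
#' @param seed Integer seed.
#' @return A list with `matrix` (samples x features, dimnames set),
#'   `annotation` (data frame `sample_id`, `category`) and `truth`
#'   (`cluster_labels`, an integer vector named by sample).
#' @export
simulate_cohort <- function(n_samples = 120L, n_features = 5L,
                            n_clusters = 3L, separation = 3,
                            annotation_association = 0.8, seed = 1L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2", call. = FALSE)
  stop_if_not_scalar_number(separation, "separation", nonneg = TRUE)
  if (annotation_association < 0 || annotation_association > 1) {
    stop("annotation_association must be in [0, 1]", call. = FALSE)
  }
  with_substream(seed, .SUBSTREAM[["cohort"]], {
    samples <- make_ids("tumor", n_samples)
    labels <- sort(rep_len(seq_len(n_clusters), n_samples))
    centers <- matrix(
      stats::rnorm(n_clusters * n_features) * 0.25 +
        outer(seq_len(n_clusters), rep(1, n_features)) * separation,
      nrow = n_clusters
    )
    m <- centers[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_samples * n_features), nrow = n_samples)
    dimnames(m) <- list(samples, make_ids("feat", n_features))
    cats <- sprintf("subtype_%d", seq_len(n_clusters))
    take_true <- stats::runif(n_samples) < annotation_association
    category <- ifelse(take_true, cats[labels],
                       sample(cats, n_samples, replace = TRUE))
    list(
      matrix = m,
      annotation = data.frame(sample_id = samples, category = category,
                              stringsAsFactors = FALSE),
      truth = list(cluster_labels = stats::setNames(labels, samples))
    )
  })
}

#' Simulate a limiting-dilution transplantation assay
#'
#' Each injection of `dose` cells responds (forms a tumor) independently with
#' probability `1 - exp(-frequency * dose)`, the single-hit Poisson model for
#' tumor-initiating cells.
#'
#' @param frequency True tumor-initiating-cell frequency (per cell, >= 0).
#' @param doses Vector of positive cell doses.
#' @param n_per_dose Injections per dose.
#' @param seed Integer seed.
#' @param group Group label attached to the assay table.
#' @return An LDAssay data frame with columns `group`, `dose`, `n_tested`,
#'   `n_responded`.
#' @export
#' @examples
#' simulate_ld_assay(1 / 500, doses = c(100, 500, 2500), n_per_dose = 6,
#'                   seed = 1)
simulate_ld_assay <- function(frequency, doses = c(100, 500, 2500),
                              n_per_dose = 6L, seed = 1L, group = "group") {
  stop_if_not_scalar_number(frequency, "frequency", nonneg = TRUE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  with_substream(seed, .SUBSTREAM[["ld"]], {
    p <- 1 - exp(-frequency * doses)
    data.frame(
      group = group, dose = doses, n_tested = as.integer(n_per_dose),
      n_responded = stats::rbinom(length(doses), n_per_dose, p),
      stringsAsFactors = FALSE
    )
  })
}

#' Evaluate the four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`; with `hill > 0`
#' this is a decreasing viability curve reaching `(top + bottom) / 2` exactly
#' at `x = ic50`.
#'
#' @param x Concentrations (> 0).
#' @param top,bottom,ic50,hill 4PL parameters; `ic50 > 0`, `hill != 0`.
#' @return Numeric vector of responses.
#' @export
fourpl_curve <- function(x, top, bottom, ic50, hill) {
  stopifnot(all(x > 0), ic50 > 0, hill != 0)
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Simulate a dose-response viability table
#'
#' Viability is the 4PL curve at each concentration plus Normal noise,
#' replicated `n_replicates` times.
#'
#' @param params Named list or vector with `top`, `bottom`, `ic50`, `hill`.
#' @param concentrations Positive concentrations (nM).
#' @param noise_sd Normal noise sd in viability units.
#' @param n_replicates Replicates per concentration.
#' @param seed Integer seed.
#' @param group Group label attached to the table.
#' @return A DoseResponseTable data frame (`group`, `concentration`,
#'   `viability`, `replicate`).
#' @export
simulate_dose_response <- function(params, concentrations, noise_sd = 0.05,
                                   n_replicates = 3L, seed = 1L,
                                   group = "group") {
  params <- as.list(params)
  if (any(concentrations <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (params$hill == 0) stop("hill must be nonzero", call. = FALSE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  with_substream(seed, .SUBSTREAM[["dose"]], {
    grid <- expand.grid(concentration = concentrations,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE)
    mu <- fourpl_curve(grid$concentration, params$top, params$bottom,
                       params$ic50, params$hill)
    data.frame(
      group = group, concentration = grid$concentration,
      viability = mu + stats::rnorm(nrow(grid), sd = noise_sd),
      replicate = grid$replicate, stringsAsFactors = FALSE
    )
  })
}
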