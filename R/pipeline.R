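# Orchestration: schema-checked tabular I/O, config validation and
# reproducible end-to-end runs over the analysis stages.

#' Read a schema-checked stage table
#'
#' Reads a TSV or CSV (dialect chosen by extension, `.csv` = comma,
#' anything else = tab, overridable) with a header row, checks that every
#' schema column is present, and parses each to its declared type. A cell
#' that fails to parse is reported with its row and column.
#'
#' @param path File path.
#' @param schema Named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`, `"logical"`. Missing values
#'   (empty or `NA`) are allowed and preserved.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return A data frame with the schema columns typed as declared (extra
#'   columns are kept as character).
#' @export
read_stage_table <- function(path, schema, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path,
                               call. = FALSE)
  sep <- if (format == "csv" ||
             (format == "auto" && grepl("\\.csv$", path, ignore.case = TRUE)))
    "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           quote = "\"", comment.char = "")
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    v <- raw[[col]]
    parsed <- switch(schema[[col]],
      character = v,
      numeric = suppressWarnings(as.numeric(v)),
      integer = suppressWarnings(as.integer(v)),
      logical = {
        out <- rep(NA, length(v))
        out[tolower(v) %in% c("true", "t", "1")] <- TRUE
        out[tolower(v) %in% c("false", "f", "0")] <- FALSE
        out
      },
      stop("unknown schema type: ", schema[[col]], call. = FALSE)
    )
    bad <- which(!is.na(v) & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("unparseable %s value in %s at row %d, column `%s`: \"%s\"",
                   schema[[col]], path, bad[1L], col, v[bad[1L]]),
           call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  raw
}

#' Write a stage table
#'
#' TSV (default) or CSV by extension; no quoting, no row names; `NA`
#' written as empty fields so a round trip through [read_stage_table()] is
#' the identity.
#'
#' @param table Data frame.
#' @param path Output path.
#' @param format `"auto"`, `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_stage_table <- function(table, path,
                              format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv" ||
             (format == "auto" && grepl("\\.csv$", path, ignore.case = TRUE)))
    "," else "\t"
  utils::write.table(as.data.frame(table), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# Known configuration keys and their defaults. The pipeline is fully
# synthetic-driven unless explicit input paths are supplied.
pipeline_defaults <- function() {
  list(
    stages = c("derepress", "profile", "stratify", "ldassay", "dose"),
    seed = 1L,
    # synthetic fold-change universe
    n_genes = 11000L, n_targets = 945L, target_shift = 0.10,
    background_sd = 0.5, n_experiments = 4L,
    # de-repression analysis
    n_bins = 10L, select = "fixed", cs_threshold = -0.15,
    # qPCR profiling
    n_assays = 40L, n_regulated = 5L, regulated_shift = 1.0,
    fc_threshold = 0.5, p_threshold = 0.05, detection_ceiling = 28,
    n_replicates = 3L,
    # cohort stratification
    n_samples = 120L, n_features = 5L, k = 3L, separation = 3,
    annotation_association = 0.8, log_transform = FALSE,
    # limiting dilution
    ld_frequency = 1 / 500, ld_frequency_b = 1 / 2500,
    ld_doses = c(100, 500, 2500), ld_n_per_dose = 6L,
    # dose response
    dr_top = 1, dr_bottom = 0, dr_ic50 = 3560, dr_ic50_test = 71,
    dr_hill = 1, dr_noise_sd = 0.02, dr_replicates = 3L,
    # optional external inputs (paths); NULL means simulate
    profiles_path = NULL, targets_path = NULL, ct_path = NULL,
    matrix_path = NULL, annot_path = NULL, ld_path = NULL, dr_path = NULL,
    group_a = "stem", group_b = "non_stem"
  )
}

#' Validate a pipeline configuration
#'
#' Materializes defaults over user-supplied keys, rejects unknown keys,
#' checks cross-field constraints (fixed bin selection requires 10 bins;
#' every referenced input path must exist) and reports all problems in a
#' single aggregated error.
#'
#' @param cfg Named list of configuration overrides (may be empty).
#' @return The validated config (class `pipeline_config`) with every
#'   default materialized.
#' @export
#' @examples
#' validate_config(list(seed = 7, n_bins = 10))$n_bins
validate_config <- function(cfg = list()) {
  defaults <- pipeline_defaults()
  problems <- character(0)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    problems <- c(problems,
                  paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(defaults, cfg[setdiff(names(cfg), unknown)])
  bad_stages <- setdiff(merged$stages,
                        c("derepress", "profile", "stratify", "ldassay",
                          "dose"))
  if (length(bad_stages)) {
    problems <- c(problems, paste0("unknown stage(s): ",
                                   paste(bad_stages, collapse = ", ")))
  }
  if (identical(merged$select, "fixed") && merged$n_bins != 10L) {
    problems <- c(problems,
                  "fixed bin selection requires n_bins = 10")
  }
  for (key in c("profiles_path", "targets_path", "ct_path", "matrix_path",
                "annot_path", "ld_path", "dr_path")) {
    paths <- merged[[key]]
    if (!is.null(paths) && !all(file.exists(paths))) {
      problems <- c(problems, paste0(key, ": path does not exist: ",
                                     paste(paths[!file.exists(paths)],
                                           collapse = ", ")))
    }
  }
  if (!is.numeric(merged$seed) || length(merged$seed) != 1L) {
    problems <- c(problems, "seed must be a single integer")
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  structure(merged, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order on synthetic inputs
#' (or supplied tables), writes every stage output as TSV under `out_dir`,
#' and returns (and writes) a JSON run summary holding the parameters
#' actually used, per-stage key statistics and md5 checksums of every
#' written file. Identical (config, inputs) give identical outputs.
#'
#' @param cfg A `pipeline_config` from [validate_config()] (or a raw list,
#'   which is validated first).
#' @param out_dir Output directory, created if absent.
#' @return The run summary (invisibly), also written to
#'   `file.path(out_dir, "run_summary.json")`.
#' @export
run_pipeline <- function(cfg = list(), out_dir = tempfile("mirstem_run_")) {
  if (!inherits(cfg, "pipeline_config")) cfg <- validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(package = "mirstem",
                  version = as.character(utils::packageVersion("mirstem")),
                  parameters = cfg[setdiff(names(cfg), "stages")],
                  stages = list())
  written <- character(0)

  scfg <- synthetic_config(
    n_genes = cfg$n_genes, n_targets = cfg$n_targets,
    target_shift = cfg$target_shift, background_sd = cfg$background_sd,
    n_experiments = cfg$n_experiments,
    detection_ceiling = cfg$detection_ceiling, seed = cfg$seed
  )

  if ("derepress" %in% cfg$stages) {
    if (is.null(cfg$profiles_path)) {
      sim <- simulate_derepression_profiles(scfg)
      profiles <- sim$profiles
      annot <- sim$annotation
    } else {
      profiles <- lapply(cfg$profiles_path, read_stage_table,
                         schema = c(gene_id = "character",
                                    log2fc = "numeric"))
      tg <- read_stage_table(cfg$targets_path,
                             schema = c(gene_id = "character",
                                        context_score = "numeric"))
      universe <- unique(profiles[[1L]]$gene_id)
      cs <- stats::setNames(rep(NA_real_, length(universe)), universe)
      cs[tg$gene_id[tg$gene_id %in% universe]] <-
        tg$context_score[tg$gene_id %in% universe]
      annot <- target_annotation(universe, unname(cs), cfg$cs_threshold)
    }
    shift <- global_shift(profiles[[1L]], annot, n_bootstrap = 200L,
                          seed = cfg$seed)
    res <- derepression_analysis(profiles, annot, n_bins = cfg$n_bins,
                                 mode = cfg$select)
    for (i in seq_along(res$enrichment)) {
      f <- file.path(out_dir, sprintf("bin_enrichment_%d.tsv", i))
      write_stage_table(as.data.frame(res$enrichment[[i]]), f)
      written <- c(written, f)
    }
    up_f <- file.path(out_dir, "consensus_up.grp")
    writeLines(res$consensus$up_genes, up_f)
    down_f <- file.path(out_dir, "consensus_down.grp")
    writeLines(res$consensus$down_genes, down_f)
    dt_f <- file.path(out_dir, "direct_targets.tsv")
    write_stage_table(data.frame(gene_id = res$direct$genes), dt_f)
    written <- c(written, up_f, down_f, dt_f)
    summary$stages$derepress <- list(
      median_shift = shift$median_shift, shift_sem = shift$sem,
      wilcoxon_p = shift$wilcoxon_p,
      n_up = length(res$consensus$up_genes),
      n_down = length(res$consensus$down_genes),
      n_direct_targets = length(res$direct$genes),
      direct_chisq = res$direct$chisq, direct_p = res$direct$p_value
    )
  }

  if ("profile" %in% cfg$stages) {
    if (is.null(cfg$ct_path)) {
      ct <- simulate_ct_experiment(
        scfg, n_assays = cfg$n_assays, n_regulated = cfg$n_regulated,
        regulated_shift = cfg$regulated_shift,
        groups = c(cfg$group_a, cfg$group_b),
        n_replicates = cfg$n_replicates)$ct
    } else {
      ct <- read_stage_table(cfg$ct_path, schema = c(
        assay_id = "character", sample_id = "character", group = "character",
        replicate = "integer", ct = "numeric", is_housekeeping = "logical"))
    }
    detected <- filter_detected(ct, cfg$detection_ceiling)
    norm <- normalize_expression(detected)
    diff <- differential_mirnas(norm, cfg$group_a, cfg$group_b,
                                cfg$fc_threshold, cfg$p_threshold)
    f <- file.path(out_dir, "differential_mirnas.tsv")
    write_stage_table(as.data.frame(diff), f)
    written <- c(written, f)
    summary$stages$profile <- list(
      n_tested = nrow(diff), n_regulated = sum(diff$regulated),
      test = attr(diff, "test"))
  }

  if ("stratify" %in% cfg$stages) {
    if (is.null(cfg$matrix_path)) {
      coh <- simulate_cohort(cfg$n_samples, cfg$n_features, cfg$k,
                             cfg$separation, cfg$annotation_association,
                             seed = cfg$seed)
      m <- coh$matrix
      ann <- coh$annotation
    } else {
      mt <- read_stage_table(cfg$matrix_path, schema = c(sample_id = "character"))
      m <- as.matrix(mt[setdiff(names(mt), "sample_id")])
      m <- apply(m, 2L, as.numeric)
      rownames(m) <- mt$sample_id
      ann <- read_stage_table(cfg$annot_path, schema = c(
        sample_id = "character", category = "character"))
    }
    cl <- ward_cluster(standardize_matrix(m, cfg$log_transform), cfg$k)
    report <- cluster_annotation_enrichment(cl, ann)
    f <- file.path(out_dir, "cluster_assignment.tsv")
    write_stage_table(data.frame(sample_id = names(cl$cluster),
                                 cluster = unname(cl$cluster)), f)
    written <- c(written, f)
    summary$stages$stratify <- list(
      k = cl$k, chisq = report$statistic, df = report$df,
      p_value = report$p_value)
  }

  if ("ldassay" %in% cfg$stages) {
    if (is.null(cfg$ld_path)) {
      a <- simulate_ld_assay(cfg$ld_frequency, cfg$ld_doses,
                             cfg$ld_n_per_dose, seed = cfg$seed,
                             group = "control")
      b <- simulate_ld_assay(cfg$ld_frequency_b, cfg$ld_doses,
                             cfg$ld_n_per_dose, seed = cfg$seed + 1,
                             group = "treated")
      tab <- rbind(a, b)
    } else {
      tab <- read_stage_table(cfg$ld_path, schema = c(
        group = "character", dose = "numeric", n_tested = "integer",
        n_responded = "integer"))
    }
    groups <- unique(tab$group)
    fits <- lapply(groups, function(g) {
      estimate_frequency(tab[tab$group == g, , drop = FALSE])
    })
    names(fits) <- groups
    est <- data.frame(
      group = groups,
      frequency = vapply(fits, `[[`, numeric(1), "frequency"),
      one_in = vapply(fits, `[[`, numeric(1), "one_in"),
      ci_lower = vapply(fits, `[[`, numeric(1), "ci_lower"),
      ci_upper = vapply(fits, `[[`, numeric(1), "ci_upper"),
      boundary = vapply(fits, `[[`, character(1), "boundary")
    )
    f <- file.path(out_dir, "ld_estimates.tsv")
    write_stage_table(est, f)
    written <- c(written, f)
    summary$stages$ldassay <- list(estimates = est)
    if (length(groups) == 2L &&
        all(est$boundary == "none")) {
      cmp <- compare_frequencies(tab[tab$group == groups[1L], ],
                                 tab[tab$group == groups[2L], ])
      summary$stages$ldassay$comparison <- list(
        fold_change = cmp$fold_change, lrt = cmp$lrt, p_value = cmp$p_value)
    }
  }

  if ("dose" %in% cfg$stages) {
    if (is.null(cfg$dr_path)) {
      conc <- 10^seq(0, 5, length.out = 8)
      ref <- simulate_dose_response(
        list(top = cfg$dr_top, bottom = cfg$dr_bottom, ic50 = cfg$dr_ic50,
             hill = cfg$dr_hill), conc, cfg$dr_noise_sd,
        cfg$dr_replicates, seed = cfg$seed, group = "reference")
      tst <- simulate_dose_response(
        list(top = cfg$dr_top, bottom = cfg$dr_bottom,
             ic50 = cfg$dr_ic50_test, hill = cfg$dr_hill), conc,
        cfg$dr_noise_sd, cfg$dr_replicates, seed = cfg$seed + 1,
        group = "test")
      tab <- rbind(ref, tst)
    } else {
      tab <- read_stage_table(cfg$dr_path, schema = c(
        group = "character", concentration = "numeric",
        viability = "numeric", replicate = "integer"))
    }
    groups <- unique(tab$group)
    fits <- lapply(groups, function(g) fit_4pl(tab[tab$group == g, ]))
    names(fits) <- groups
    est <- data.frame(
      group = groups,
      t(vapply(fits, coef, numeric(4))),
      converged = vapply(fits, `[[`, logical(1), "converged")
    )
    f <- file.path(out_dir, "fourpl_fits.tsv")
    write_stage_table(est, f)
    written <- c(written, f)
    summary$stages$dose <- list(fits = est)
    if (length(groups) == 2L && all(est$converged)) {
      pr <- relative_potency(tab[tab$group == groups[1L], ],
                             tab[tab$group == groups[2L], ])
      summary$stages$dose$relative_potency <- list(
        ratio = pr$ratio, ci = pr$ci, ratio_free = pr$ratio_free)
    }
  }

  summary$checksums <- as.list(tools::md5sum(written))
  names(summary$checksums) <- basename(written)
  json_path <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(summary)
}
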