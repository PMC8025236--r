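# qPCR profiling: detection filter, delta-Ct normalization, differential
# calling, overlap test and protocol arithmetic.

test_that("detection filter keeps only Ct strictly below the ceiling", {
  ct <- make_ct_table(list(a = c(25.1, 29.3, NA)))
  out <- suppressMessages(filter_detected(ct))
  expect_equal(out$ct[out$assay_id == "a"], 25.1)

  # boundary behaviour under the strict-< rule, checked by a linear scan
  vals <- c(27.99, 28.0, 28.01, 26.5, 30.0)
  ct2 <- data.frame(assay_id = paste0("m", 1:5), sample_id = "s1",
                    group = "g", replicate = 1L, ct = vals,
                    is_housekeeping = FALSE)
  out2 <- suppressMessages(filter_detected(ct2))
  expect_equal(nrow(out2), sum(vals < 28))
  expect_setequal(out2$assay_id, paste0("m", which(vals < 28)))

  all_na <- data.frame(assay_id = "a", sample_id = "s1", group = "g",
                       replicate = 1L, ct = NA_real_,
                       is_housekeeping = FALSE)
  expect_warning(out3 <- suppressMessages(filter_detected(all_na)),
                 "all measurements")
  expect_equal(nrow(out3), 0L)
})

test_that("Ct table invariants are enforced", {
  bad <- data.frame(assay_id = "a", sample_id = "s1", group = "g",
                    replicate = c(1L, 1L), ct = c(20, 21),
                    is_housekeeping = FALSE)
  expect_error(filter_detected(bad), "unique")
  expect_error(filter_detected(bad[, -5]), "missing column")
  oor <- data.frame(assay_id = "a", sample_id = "s1", group = "g",
                    replicate = 1L, ct = 50, is_housekeeping = FALSE)
  expect_error(filter_detected(oor), "\\(0, 45\\]")
})

test_that("normalization subtracts the per-sample housekeeping median", {
  # three housekeeping assays: median of {19.8, 20.0, 20.6} = 20.0
  ct <- data.frame(
    assay_id = c("hk1", "hk2", "hk3", "a", "b"), sample_id = "s1",
    group = "g", replicate = 1L, ct = c(19.8, 20.0, 20.6, 24, 20),
    is_housekeeping = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  norm <- normalize_expression(ct)
  expect_equal(norm$delta_ct[norm$assay_id == "a"], 4)        # 24 - 20
  expect_equal(norm$rel_expr[norm$assay_id == "a"], 0.0625)   # 2^-4
  expect_equal(norm$delta_ct[norm$assay_id == "b"], 0)        # identity
  expect_equal(norm$rel_expr[norm$assay_id == "b"], 1)

  no_hk <- ct[!ct$is_housekeeping, ]
  expect_error(normalize_expression(no_hk), "s1")
})

test_that("normalization is invariant to a constant shift of a sample", {
  ct <- make_ct_table(list(a = c(24, 24.5), b = c(22, 23)), hk_ct = 20)
  norm0 <- normalize_expression(ct)
  shifted <- ct
  shifted$ct[shifted$sample_id == "s1"] <-
    shifted$ct[shifted$sample_id == "s1"] + 3
  expect_equal(normalize_expression(shifted)$delta_ct, norm0$delta_ct)
})

test_that("differential calling matches the Welch t oracle and is strict", {
  norm <- make_norm_table(list(
    A = list(m1 = c(4.0, 4.1, 3.9)), B = list(m1 = c(5.0, 5.1, 4.9))))
  res <- differential_mirnas(norm, "A", "B")
  expect_equal(res$log2fc, 1.0)
  # Welch oracle computed from first principles
  a <- c(4.0, 4.1, 3.9); b <- c(5.0, 5.1, 4.9)
  se2 <- var(a) / 3 + var(b) / 3
  tstat <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df))
  expect_true(res$regulated)

  # identical groups: zero fold-change, never regulated
  same <- make_norm_table(list(A = list(m1 = c(4, 4.2, 4.4)),
                               B = list(m1 = c(4, 4.2, 4.4))))
  res2 <- differential_mirnas(same, "A", "B")
  expect_equal(res2$log2fc, 0)
  expect_false(res2$regulated)

  # |log2fc| exactly at the threshold is NOT regulated (strict inequality)
  # binary-exact quarters keep the fold-change at exactly 0.5
  exact <- make_norm_table(list(A = list(m1 = c(4.0, 4.0625, 3.9375)),
                                B = list(m1 = c(4.5, 4.5625, 4.4375))))
  res3 <- differential_mirnas(exact, "A", "B")
  expect_identical(res3$log2fc, 0.5)
  expect_lt(res3$p_value, 0.05)
  expect_false(res3$regulated)
})

test_that("fold-change is antisymmetric in the group order", {
  sim <- simulate_ct_experiment(synthetic_config(seed = 21), n_assays = 8,
                                n_regulated = 3)
  norm <- normalize_expression(suppressMessages(filter_detected(sim$ct)))
  ab <- differential_mirnas(norm, "stem", "non_stem")
  ba <- differential_mirnas(norm, "non_stem", "stem")
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("assays with too few replicates are skipped with a warning", {
  norm <- make_norm_table(list(A = list(m1 = c(4, 4.1), m2 = 5),
                               B = list(m1 = c(5, 5.1), m2 = c(5, 6))))
  expect_warning(res <- differential_mirnas(norm, "A", "B"), "m2")
  expect_identical(res$assay_id, "m1")
})

test_that("overlap test equals the exhaustive hypergeometric tail", {
  u <- as.character(1:100)
  res <- overlap_test(u[1:10], u[8:17], u)
  expect_identical(res$overlap_count, 3L)
  expect_equal(res$p_value, hyper_tail_oracle(3, 10, 10, 100))

  # random small instances, exhaustively enumerated
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    uni <- as.character(seq_len(n))
    a <- sample(uni, sample(1:n, 1))
    b <- sample(uni, sample(1:n, 1))
    res <- overlap_test(a, b, uni)
    expect_equal(res$p_value,
                 hyper_tail_oracle(res$overlap_count, length(a), length(b), n))
  }

  # identical sets attain the minimal (fully overlapping) p
  res_eq <- overlap_test(u[1:10], u[1:10], u)
  expect_equal(res_eq$p_value, hyper_tail_oracle(10, 10, 10, 100))
  # disjoint small sets in a large universe: p ~ 1
  expect_gt(overlap_test(u[1:3], u[50:52], u)$p_value, 0.9)
  expect_error(overlap_test("x", "y", character(0)), "universe")
})

test_that("null Ct data are called at close to the nominal rate", {
  # zero planted effect: fraction of regulated calls bounded by the
  # p threshold plus a 3-sigma binomial allowance
  calls <- unlist(lapply(1:200, function(s) {
    sim <- simulate_ct_experiment(synthetic_config(seed = s),
                                  n_assays = 10, n_regulated = 0)
    norm <- normalize_expression(suppressMessages(filter_detected(sim$ct)))
    differential_mirnas(norm, "stem", "non_stem")$regulated
  }))
  n <- length(calls)
  expect_lte(mean(calls), 0.05 + 3 * sqrt(0.05 * 0.95 / n))
})

test_that("planted 1-cycle shifts are recovered at the power the test admits", {
  # At 3 replicates and 0.25-cycle noise a two-sided Welch t on a 1-cycle
  # shift has limited power (~0.88 even without housekeeping noise), so
  # recovery is checked against a 70% floor.
  hits <- 0; total <- 0
  for (s in 1:60) {
    sim <- simulate_ct_experiment(synthetic_config(ct_tech_sd = 0.25,
                                                   seed = s),
                                  n_assays = 20, n_regulated = 5,
                                  regulated_shift = 1.0, n_replicates = 3)
    norm <- normalize_expression(suppressMessages(filter_detected(sim$ct)))
    d <- differential_mirnas(norm, "stem", "non_stem")
    hits <- hits + sum(d$assay_id[d$regulated] %in%
                         sim$truth$regulated_assays)
    total <- total + length(sim$truth$regulated_assays)
  }
  expect_gte(hits / total, 0.70)
})

test_that("dilution and loading arithmetic matches the protocol table", {
  expect_identical(composite_dilution_factor(c(4, 20)), 80)
  expect_identical(composite_dilution_factor(c(4, 50)), 200)
  expect_identical(composite_dilution_factor(numeric(0)), 1)
  expect_error(composite_dilution_factor(c(4, 0.5)), ">= 1")

  expect_equal(rip_loading_fraction(200, 100), 10)
  expect_equal(rip_loading_fraction(0, 100), 0)
  expect_equal(rip_loading_fraction(50, 1000, input_fraction = 1), 5)
  expect_error(rip_loading_fraction(10, 0), "input_copies")
})
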