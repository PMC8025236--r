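---
title: "Methods: quantifying miRNA-driven stem-cell biology with mirstem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying miRNA-driven stem-cell biology with mirstem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstem)
```

# Overview

`mirstem` implements the quantitative backbone of a miRNA loss-of-function
study in mammary stem cells (SCs): how a miRNA family restrains the
stem-cell compartment, and what happens — transcriptionally, functionally
and pharmacologically — when it is lost. The package covers five analysis
stages, each usable on its own:

1. **qPCR miRNA profiling** — from raw TaqMan cycle-threshold (Ct) tables
   to differentially expressed miRNAs between sorted cell populations.
2. **Cohort stratification** — Ward clustering of tumor cohorts on
   standardized miRNA-signature expression, with cluster-by-annotation
   contingency analysis.
3. **Target de-repression** — the core inference: nominating direct miRNA
   targets from the subtle, genome-wide up-shift of predicted targets
   after miRNA loss, via ranked equal-count bins.
4. **Limiting-dilution analysis** — tumor-initiating-cell (TIC) frequency
   under the single-hit Poisson model, ELDA-style.
5. **Dose–response** — four-parameter logistic (4PL) fitting, IC50 and
   relative potency between conditions.

A synthetic-data module generates every input with planted ground truth, so
each estimator can be validated against what was simulated.

# qPCR profiling model

Raw Ct values are filtered at a detection ceiling of 28 cycles. The
exclusion rule is *strict*: a measurement survives only if `ct < 28`. The
two informal conventions in circulation ("exclude above 28", "keep below
28") leave equality undefined; we exclude Ct = 28 as the conservative
choice, since a measurement at the ceiling carries no evidence of reliable
amplification.

Expression is normalized per sample by the **median of the housekeeping
controls**: `delta_ct = ct − median(housekeeping Ct)`, with relative
expression `2^(−delta_ct)`. Because the housekeeping median is a per-sample
constant, adding any constant to all Ct values of a sample leaves
`delta_ct` unchanged (an invariance the test suite checks).

Differential calling between two groups uses the log2 fold-change
`mean(ΔCt_B) − mean(ΔCt_A)` (one cycle = one log2 unit; lower ΔCt means
higher expression) and a **two-sided Welch t-test** on the per-replicate
ΔCt values. The criterion is strict on both sides: `|log2FC| > 0.5` *and*
`p < 0.05` on the raw p-value. No multiple-testing correction is applied by
default, matching the raw-p convention of miRNA screening panels; a
Benjamini–Hochberg option (`adjust = "BH"`) is exposed. Assays detected in
only one group are excluded rather than imputed — no defensible imputation
rule exists for "not amplified".

**Power at screening scale.** At 3 replicates per group, technical noise of
0.25 cycles and a planted 1-cycle shift, a two-sided Welch t-test has
limited power: about 0.88 in the idealized case, and about 0.77 once the
housekeeping-median noise propagates into ΔCt. The property suite therefore
asserts recovery above a 70% floor at these conditions; near-complete
recovery (>99%) requires roughly 6 replicates per group. This is an
inherent small-sample property of the test, not an implementation limit.

Overlap between regulated-miRNA sets from different model systems is tested
with the one-sided (enrichment) **Fisher's exact test** against the
hypergeometric null on a shared assay universe.

Two protocol helpers round out the stage: `composite_dilution_factor()`
(the final dilution of a serial protocol is the product of its steps, e.g.
1:4 × 1:20 = 1:80 for the low-sample-input protocol vs 1:4 × 1:50 = 1:200
for the standard one) and `rip_loading_fraction()` (percentage of total
miRNA copies loaded on an immunoprecipitated complex, accounting for the
input lane assaying only a fraction — by default 5% — of the lysate).

# Cohort stratification

Tumor cohorts are stratified on a small miRNA signature: each feature is
z-scored (`standardize_matrix()`; an optional `log2(x + 1)` transform is
provided for reads-per-million matrices, because public cohort matrices do
not document their scale — the flag is the caller's decision), then samples
are clustered with **Ward's minimum-variance criterion** on Euclidean
distances (`hclust(method = "ward.D2")`, the classical Lance–Williams form
with squared Euclidean distances inside the criterion). The number of
clusters `k` is always user-supplied — published stratifications fixed 2 or
3 clusters by inspection — and `suggest_k()` offers an advisory silhouette
score that is never auto-applied.

Association between clusters and a categorical annotation (molecular
subtype, receptor status, …) is tested with the global **Pearson
chi-square** without continuity correction, `df = (r−1)(c−1)`. Per-cell
enrichment and depletion calls use standardized (adjusted) residuals
`(O − E)/sqrt(E(1 − row margin)(1 − col margin))` flagged at `|z| > 1.96`;
published figures star per-category effects without naming a post-hoc
method, and adjusted residuals are the standard choice for that purpose.

# Ranked-bin target de-repression

Transcriptional effects of miRNA loss are typically mild — a median shift
of about +0.10 log2 units for predicted targets — so fold-change cutoffs
miss most direct targets. The package instead:

1. **Quantifies the global shift** (`global_shift()`): the median log2FC of
   predicted targets minus that of all other genes, with a seeded
   bootstrap SEM and a two-sided Wilcoxon rank-sum p-value (normal
   approximation; exact enumeration is infeasible and ill-defined with
   ties at transcriptome scale).
2. **Ranks and bins** (`rank_and_bin()`): genes sorted by log2FC
   descending; bin 1 holds the most up-regulated genes. With 11,000 genes
   and 10 bins every bin holds exactly 1,100 genes. Bin sizes are
   `floor(N/B)` with the remainder assigned one gene each to the
   lowest-index bins, and fold-change ties are broken lexicographically by
   gene id, making the partition deterministic and total.
3. **Scores per-bin enrichment** (`bin_enrichment()`): observed vs expected
   target counts per bin (`expected = bin size × target fraction`),
   reported as `log2(observed/expected)`. A pseudo-count of 0.5 enters
   numerator and denominator *only* when a bin holds zero targets, keeping
   the ratio finite while leaving all other bins untouched. The per-bin
   p-value comes from the Pearson chi-square on the 2×2 (in bin vs rest) ×
   (target vs not) table, replaced by Fisher's exact test whenever any
   expected cell drops below 5.
4. **Selects bins** (`select_bins()`): the fixed split takes bins 1–4 as
   target-enriched and 7–10 as depleted (the canonical choice for a 10-bin
   ranking of a de-repression experiment); the adaptive mode instead takes
   the maximal significant prefix/suffix and is useful away from the
   default geometry.
5. **Intersects across experiments** (`consensus_sets()`): strict
   intersection over *all* experiments of the top-bin genes (commonly
   up-regulated) and bottom-bin genes (commonly down-regulated); pairwise
   Fisher overlap p-values are reported as diagnostics.
6. **Nominates direct targets** (`direct_targets()`): consensus up-genes ∩
   predicted targets, with a df = 1 Pearson chi-square on the 2×2 of
   target status × consensus membership over the full universe.

The prediction annotation consumes a TargetScan-style context-score table;
genes with a score strictly below −0.15 count as predicted targets. Context
scores are consumed, never recomputed.

# Limiting-dilution analysis

Under the single-hit model, a transplant takes if it received at least one
tumor-initiating cell: `P(take | dose d) = 1 − exp(−f·d)`. On the
complementary log-log scale this is linear in `log d` with slope exactly 1,
so the maximum-likelihood estimate of `f` is a **binomial GLM with cloglog
link and log-dose offset** — the ELDA formulation. Confidence intervals are
Wald on `log f` by default (matching ELDA-style reporting), with a
profile-likelihood option. Frequencies are reported both as `f` and as
"1 in `1/f` cells".

Saturated assays are *flagged, not refused*: with zero responders the MLE
is 0 and a 95% upper bound solves `P(no response | f) = 0.05`; with all
responders a lower bound solves `P(all respond | f) = 0.05`. Group
comparison uses the likelihood-ratio test (df = 1) of a shared versus
group-specific frequency — better behaved than a Wald test at the small
counts of transplantation tables — plus the frequency fold-change. Model
adequacy is checked by freeing the slope on `log(dose)` and Wald-testing
slope = 1.

**Interval calibration.** Over 2,000 simulated assays (three doses
100/500/2,500, ten injections per dose, true frequency 1/500) the default
Wald interval covers the truth 96% of the time. At six injections per dose
the Wald interval is slightly anticonservative (~92% coverage) while the
profile-likelihood interval holds 96%; for very small designs the profile
interval is the better choice, and both are exposed.

Two phenotype formulas accompany the stage: sphere-forming efficiency
(`100 × spheres/cells plated`) and ellipsoid tumor volume (`L·W²/2` with
`L ≥ W`; swapped inputs are corrected with a warning).

# Dose–response analysis

Viability curves are fitted with the four-parameter logistic
`y = bottom + (top − bottom)/(1 + (x/IC50)^hill)` by bounded
Levenberg–Marquardt least squares (unweighted — the common default of
"Logistic 4P" style fitters) on log-concentration for conditioning.
Initialization is deterministic: `top = max(y)`, `bottom = min(y)`, IC50 at
the geometric mid-concentration, `hill = 1`; the convergence tolerance is
1e-8 on the relative residual-sum-of-squares change; IC50 is bounded to
[min conc/100, max conc×100] and the Hill slope to [0.1, 10]. Ascending
(activation-like) data are detected from a linear screen on
log-concentration and fitted as the reflected curve, recorded in the fit's
`direction` field. Flat responses leave IC50 unidentifiable and return a
degenerate-flagged fit rather than an arbitrary number. By construction the
fitted response at `x = IC50` is exactly `(top + bottom)/2`.

**Relative potency** between a reference and a test condition uses a
shared-shape *parallel* fit: common top, bottom and Hill slope with a
group-specific log-IC50 shift; the potency ratio is `exp(shift)` with a
Wald CI from the shift's standard error. The ratio of independently fitted
IC50s is reported alongside. Shape heterogeneity is screened by an F-test
of the constrained against the two free fits; at `p < 0.01` a warning is
attached but the ratio is still reported, since parallel-fit potency is
conventionally quoted even for imperfectly parallel curves.
`fold_sensitivity()` is the plain IC50 ratio — e.g. IC50s of 3,560 vs 71 nM
give a 50.1-fold sensitivity difference.

# The synthetic-data generators

Each generator emulates the statistical structure one stage consumes, with
the planted truth returned alongside:

- **Fold-change profiles**: non-targets `Normal(0, 0.5)` in log2 units;
  targets the same plus a planted shift (+0.10 by default); defaults of
  11,000 genes, 945 predicted targets and 4 independent experiments mirror
  a transcriptome-scale de-repression study. Planted targets receive
  context scores uniform in [−0.60, −0.15) — below the prediction
  threshold; the magnitude is never used downstream. The background SD of
  0.5 log2 units is a free default (per-gene dispersion is rarely
  reported) and remains configurable.
- **Ct tables**: housekeeping assays at 20 cycles, miRNA assays uniform in
  [21, 25.5], technical noise `Normal(0, 0.25)` cycles, regulated assays
  shifted by a configurable number of cycles in one group with random
  sign, and a configurable dropout fraction pushed above the detection
  ceiling.
- **Cohorts**: cluster-structured Gaussian features with means separated
  by a configurable number of within-cluster SDs, and one categorical
  annotation matching the true cluster with a configurable probability.
- **Limiting-dilution assays**: independent Bernoulli takes at
  `1 − exp(−f·dose)` (binomial per dose row).
- **Dose–response tables**: the 4PL curve plus `Normal(0, noise_sd)`
  viability noise.

Noise families are deliberately minimal — Normal for Ct, log2FC and
viability, Bernoulli/binomial for takes — because these are exactly the
assumptions the downstream statistics make. Passing tests on these
generators therefore validates the estimators *under their own model*; it
does not certify behaviour under real-data pathologies (heavy-tailed
fold-changes, amplification artefacts, batch structure, non-parallel
dose–response shapes), which is the main limitation to keep in mind.

Determinism: every generator expands the user seed into a per-generator
substream by a fixed offset, restoring the caller's RNG state afterwards.
Identical seeds give bit-identical outputs, and adding a new generator
never perturbs existing streams.

# Numerical and design choices

- Ct exactly at the detection ceiling is excluded (conservative reading of
  an ambiguous convention).
- Fold-change ties in ranking are broken by gene id; remainder genes go to
  the lowest-index bins.
- The bin-enrichment pseudo-count (0.5) applies only to zero-target bins.
- Consensus is the strict intersection across all experiments; a
  majority-vote variant was considered and rejected as the default because
  the published intersections are described as overlaps of *all*
  experiments.
- The chi-square accompanying the direct-target set is the documented 2×2
  Pearson statistic over the profiled universe; published values of this
  statistic are not always reconstructible from printed marginals, so the
  package reports what its own 2×2 implies.
- LD group comparison by LRT rather than Wald; boundary tables get
  one-sided bounds rather than errors.
- 4PL fitting is unweighted least squares; the weighting scheme of
  proprietary "Logistic 4P" scripts is undocumented, and the choice is
  recorded in the fit metadata.

# Problem sizes used in the validation suite

The test and acceptance runs use transcriptome-scale universes (11,000
genes) where the property under test concerns the default geometry, and
reduced universes (500–4,000 genes), 50–500 seed replicates, 2,000
simulated LD assays and 100–200 noisy dose–response fits elsewhere. These
sizes were chosen so the full validation cycle completes in a few minutes
on one CPU while keeping every Monte-Carlo bound at least 3 sigma away
from its threshold under the planted conditions.

# A worked end-to-end run

```{r, eval = FALSE}
library(mirstem)
res <- run_pipeline(list(seed = 1), out_dir = "mirstem_run")
res$stages$derepress$median_shift     # ~0.10 planted shift recovered
res$stages$derepress$n_direct_targets # non-empty direct-target set
res$stages$ldassay$comparison         # ~5-fold TIC frequency difference
res$stages$dose$relative_potency      # ~50-fold potency ratio
```

The run writes every stage table as TSV plus a JSON summary with the
materialized parameters and md5 checksums; re-running the same
configuration reproduces the checksums bit for bit.
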