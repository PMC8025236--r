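# mirstem

Quantitative analysis of miRNA-driven mammary stem-cell biology, in one R
package. `mirstem` is written for researchers who quantify cancer stem
cells (CSCs): it takes the recurring statistical tasks of a miRNA
loss-of-function study — from raw qPCR plates to tumor-initiating-cell
(TIC) frequencies and drug-potency ratios — and implements them as tested,
reusable functions with a synthetic-data module that lets every stage be
validated against planted ground truth.

## What it computes

**qPCR miRNA profiling.** Raw TaqMan Ct tables are detection-filtered
(`ct < 28`), normalized per sample over the median of housekeeping
controls (ΔCt; relative expression `2^(−ΔCt)`), and screened for regulated
miRNAs with a two-sided Welch t-test at the strict criterion
`|log2FC| > 0.5` and `p < 0.05`. Regulated sets from different model
systems are compared with the one-sided Fisher's exact overlap test.

**Cohort stratification.** Tumor cohorts are clustered on standardized
miRNA-signature expression with Ward's minimum-variance criterion, and
cluster-by-annotation association is tested by Pearson χ² with per-cell
standardized residuals flagged at |z| > 1.96.

**Ranked-bin target de-repression** (the core method). Losing a miRNA
de-represses its direct targets only subtly — a median shift of about
+0.10 log2 units — so instead of a fold-change cutoff, each experiment's
genes are ranked by log2 fold-change and split into 10 equal-count bins
(11,000 genes → 1,100 genes/bin). Predicted-target enrichment per bin is
scored as `log2(observed/expected)` with a contingency p-value; enriched
top bins (1–4) and depleted bottom bins (7–10) are intersected across all
experiments, and the consensus up-set is crossed with the target
prediction (context score < −0.15) to nominate high-confidence direct
targets, with a df = 1 Pearson χ².

**Limiting-dilution analysis.** TIC frequency under the single-hit model
`P(take | dose) = 1 − exp(−f·dose)`, fitted ELDA-style as a binomial GLM
with complementary log-log link and log-dose offset; Wald or
profile-likelihood CIs, one-sided bounds for saturated assays, LRT group
comparison, and a slope test of the single-hit assumption. Helpers for
sphere-forming efficiency (`100·spheres/plated`) and caliper tumor volume
(`L·W²/2`).

**Dose–response.** Four-parameter logistic fits
`y = bottom + (top − bottom)/(1 + (x/IC50)^hill)` by bounded
Levenberg–Marquardt, IC50 extraction, shared-shape parallel-fit relative
potency, and plain fold-sensitivity ratios.

## Worked example

```r
library(mirstem)

## A transcriptome-scale de-repression experiment with planted truth:
## 11,000 genes, 945 predicted targets shifted by +0.10 log2 units.
sim <- simulate_derepression_profiles(synthetic_config(seed = 1))

global_shift(sim$profiles[[1]], sim$annotation, n_bootstrap = 200, seed = 1)
#> Target de-repression: median log2FC shift +0.0884 ± 0.0189 SEM
#>   (targets n = 945 vs others n = 10055)
#>   Wilcoxon rank-sum p = 7.78e-08
```

The estimated shift (+0.088 ± 0.019) recovers the planted +0.10, and the
rank-sum test confirms targets sit significantly above the background.
Binning makes the same signal local and selectable:

```r
res <- derepression_analysis(sim$profiles, sim$annotation, mode = "fixed")
head(res$enrichment[[1]], 3)
#>   bin gene_count observed_targets expected_targets log2_obs_exp   p_value
#> 1   1       1100              128             94.5      0.43776 0.0001451
#> 2   2       1100              110             94.5      0.21912 0.0787606
#> 3   3       1100               96             94.5      0.02272 0.8649145

res$consensus
#> Consensus regulated genes over 4 experiments:
#>   commonly up-regulated:   294 genes
#>   commonly down-regulated: 309 genes

res$direct
#> Direct-target set: 46 genes
#>   target status x consensus-up: chi-square = 19.15, p = 1.21e-05
```

Bin 1 (the most up-regulated 1,100 genes) holds 128 predicted targets
against 94.5 expected; intersecting bins 1–4 across the four experiments
and crossing with the prediction yields 46 direct targets, far more than
independence allows. A limiting-dilution assay closes the loop on the
functional side:

```r
ld <- simulate_ld_assay(1/500, doses = c(100, 500, 2500),
                        n_per_dose = 10, seed = 42)
estimate_frequency(ld)
#> Single-hit limiting-dilution fit
#>   frequency: 0.001702  (1 in 587 cells)
#>   95% CI: 1 in 312 to 1 in 1107

fold_sensitivity(3560, 71)   # IC50 ratio, resistant vs sensitive
#> [1] 50.14085
```

The planted frequency of 1 TIC in 500 cells is estimated at 1 in 587 with
a covering interval, and two IC50s of 3,560 and 71 nM correspond to a
50.1-fold sensitivity difference.

A full synthetic run of all five stages, with TSV outputs and a JSON
summary (parameters, key statistics, md5 checksums):

```r
res <- run_pipeline(list(seed = 1), out_dir = "mirstem_run")
```

A thin command-line wrapper with `simulate`, `profile`, `stratify`,
`derepress`, `ldassay`, `dose` and `run` subcommands lives at
`inst/scripts/mirstem-cli.R`.

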