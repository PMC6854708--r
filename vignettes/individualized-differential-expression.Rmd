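---
title: "Individualized differential expression for matched tumor trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized differential expression for matched tumor trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idaseq)
```

## The problem

Cohorts of matched tumor trios — one adjacent normal, one primary tumor and
one metastatic lesion (here a portal vein tumor thrombus, PVTT) per patient —
pose a differential-expression problem that group-level tools cannot answer:
*which genes changed between this patient's primary tumor and this patient's
metastasis?* There are no replicates within a patient, and pooling patients
erases exactly the per-patient heterogeneity of interest: progression paths
differ so much between patients that a cohort-level contrast averages them
away.

The approach implemented here substitutes a *variance model learned from the
cohort's pooled adjacent normals* for the missing replicates. Adjacent normal
tissue varies between patients by biology and by measurement; treating the
inter-normal spread at a given expression level as the reference scale yields
a per-gene, per-patient test that needs only one pair of observations.

## The model

Let \(e^p_{ij}\) and \(e^t_{ij}\) be the normalized log2 expression of gene
\(i\) in patient \(j\)'s primary tumor and PVTT. The package uses
\(e = \log_2(\mathrm{CPM} + 1)\) (`normalize_log_cpm()`): the paired statistic
below is a difference of logs, so any depth-free log-scale quantity works, and
log2(CPM + 1) is the most widely used such scale. The test statistics are

\[
d_{ij} = e^p_{ij} - e^t_{ij}, \qquad
\mu_{ij} = \tfrac{1}{2}\!\left(e^p_{ij} + e^t_{ij}\right), \qquad
z_{ij} = \frac{d_{ij}}{\sqrt{2\,\sigma^2|_{\mu_{ij}}}},
\]

where \(\sigma^2|\mu\) is the variance of a *single* measurement conditional
on its mean, estimated from the pooled normals; the factor 2 is the variance
of a difference of two independent measurements. \(z_{ij}\) is referred to
the standard normal two-sided (both up- and down-regulated genes are of
interest), p-values are Benjamini–Hochberg adjusted *within each patient*,
and `q < 0.1` defines that patient's calls. A positive \(d\) (higher in the
primary) is reported as direction `"down"` — directions are PVTT-relative.

### The variance trend

`fit_variance_trend()` computes each gene's mean and unbiased variance across
the normals, sorts genes by mean, cuts them into `n_bins = 50` equal-count
bins, and represents \(\sigma^2|\mu\) as the piecewise-linear interpolant
through (median mean, aggregated variance) per bin, constant beyond the outer
bins and floored at `variance_floor = 1e-4` (preventing infinite z on flat
genes). Fifty bins keep \(\ge 100\) genes per bin for transcriptome-sized
inputs, enough that bin noise is a few percent.

Bin variances are aggregated by the **mean**, not the median. With \(n = 19\)
normals a per-gene variance estimate is distributed
\(\sigma^2 \chi^2_{18}/18\): its median is ~3.7% below \(\sigma^2\) and the
sample median of a bin is ~25% noisier than the mean, so a median-aggregated
trend is biased low (anti-conservative z) and misses a 10% recovery tolerance
on clean homoscedastic input. The mean is unbiased; robustness to a few
high-variance outlier genes can be recovered with `aggregate = "median"` when
the normal pool is suspected to be contaminated, at the cost of that bias.

Patient-to-patient differences are *not* removed before computing the
per-gene variance. This is deliberate: the inter-normal variation is the
method's reference scale. Because the paired difference \(d\) cancels effects
shared by both tumor samples of a patient, the trend over-covers \(d\)
whenever true patient effects are present — the test is then conservative,
which is the intended safeguard against over-calling with two observations.

### Recurrence and the permutation FDR

`recurrence_counts()` tallies, per gene, the number of patients in which it
was called (`freq`), split by direction. `permutation_fdr()` attaches a
one-sided empirical FDR to each recurrence threshold \(k\): in each of `B`
permutations every patient's call-indicator vector is shuffled across genes —
preserving that patient's call burden, which spans orders of magnitude
between patients and is the dominant nuisance — while destroying gene
identity, which is exactly the quantity under test. Then

\[
\mathrm{FDR}(k) = \min\!\left(1,\;
  \frac{\overline{N}_{\mathrm{null}}(k)}{\max(N_{\mathrm{obs}}(k), 1)}\right),
\]

made non-increasing in \(k\) by a cumulative minimum. Under this scheme the
null recurrence of a fixed gene is exactly Poisson-binomial with
\(p_j = c_j / m\); the test suite verifies the permutation estimate against
that closed form computed by dynamic programming. Thresholds no permutation
reaches are reported as the upper bound \(1/(B\,N_{\mathrm{obs}})\) and
flagged rather than printed as zero; thresholds with no observed gene are NA.
Whether "recurrent" should additionally require a shared direction is
genuinely ambiguous, so both modes exist (`direction_consistent`), counting
any call by default.

```{r recurrence-demo}
sim <- simulate_trio_cohort(sim_config(n_genes = 600, seed = 42))
e <- normalize_log_cpm(sim$counts)
normals <- sim$samples$sample_id[sim$samples$tissue == "normal"]
ef <- filter_low_expression(e, samples = normals)
trend <- fit_variance_trend(ef[, normals], n_bins = 20)
de <- run_idaseq(ef, sim$samples, trend)
pf <- permutation_fdr(de, B = 200, seed = 1)
head(pf$fdr_table[pf$fdr_table$n_obs > 0, ])
```

## The integrative driver screen

Candidate drivers are genes whose expression tracks a genomic or epigenomic
lesion across tumor samples (primaries and PVTTs):

* **Copy number.** `map_genes_to_cnv()` summarizes SEG segment means over
  each gene body by length-weighted mean and discretizes at ±0.2 (single
  gain/loss) and ±1.0 (double), inclusive at the boundaries; the thresholds
  are explicit configuration because segmentation platforms leave them to the
  caller. `spearman_screen(side = "positive")` flags genes with Spearman
  \(\rho > 0.4\) and one-sided \(p < 0.05\).
* **Promoter methylation.** Promoters are TSS−1500 to TSS+500, strand-aware
  (for a minus-strand gene "upstream" lies at larger coordinates);
  `call_hypermethylated_promoters()` requires q < 1e-4 *and* tumor-minus-
  normal \(\Delta\beta > 0.2\) on at least two promoter probes, with a paired
  t-test on beta differences standing in for array-specific engines (the
  thresholds, not the engine, are the contract). The expression screen runs
  per promoter probe with `side = "negative"` (\(\rho < -0.4\)); a gene
  qualifies on its best probe. The best-probe rule buys sensitivity at the
  cost of a selection effect on the null — the suite quantifies that rate
  against a label-permutation oracle rather than pretending it is 0.05.
* **Second order.** `second_order_independence()` correlates the two
  per-gene \(\rho\) vectors and tests candidate-set overlap by Fisher's exact
  test; `arm_enrichment()` reports, per chromosome arm, both binomial tails
  \(P(X \ge x)\) and \(P(X \le x)\) at the arm's universe proportion.

Spearman one-sided p-values use the exact null distribution for \(n < 10\)
without ties and the t-approximation otherwise — cohorts of 12–38 tumor
samples sit comfortably in the approximation's range while tiny worked
examples stay exact. Constant covariates (zero rank variance) are excluded
and logged, not silently given \(\rho = 0\).

## Arm-level CNV summaries and cohort statistics

`arm_level_calls()` computes, per sample and arm, the length-weighted mean
segment log2 ratio and the fraction of the arm covered by gained/lost
segments; a call needs both the mean beyond ±0.1 and ≥ 50% supporting
coverage. The cohort z standardizes the mean arm log-ratio by the
genome-wide SD of sample-arm means over \(\sqrt{n}\) — a documented stand-in
with the same cutoff semantics (frequency ≥ 0.5 and |z| ≥ 1.5) as
segmentation-suite internals that are not published.
`focal_frequency_compare()` is the two-cohort Fisher comparison with the
probability-mass two-sided convention (the dominant one; the doubling
convention differs in the third decimal and is not used).

`pairwise_distances()` measures transcriptome heterogeneity as
1 − Spearman \(\rho\), either within a tissue group or between matched
samples per patient; `compare_distance_sets()` applies the rank-sum test
(exact up to n = 10 per group and no ties). The simulator property that the
mean matched primary–PVTT distance falls below the inter-patient
primary–primary distance — intra-patient progression smaller than
inter-patient heterogeneity — is asserted in the test suite.

## The synthetic cohort generator

`simulate_trio_cohort()` is first-class, tested code: it defines the study
conditions under which every statistical guarantee is demonstrated. Counts
are negative binomial with mean \(s_k\,2^{g_i + a_{ij} + \Delta_{ijk}}\) and
dispersion \(\phi(\mu) = a/\mu + b\):

* `n_patients = 19`, one normal/primary/pvtt trio each;
* \(g_i \sim N(3, 2^2)\) log2 baseline — a realistic log-expression spread
  with a low-expression tail exercising the filter;
* \(a_{ij} \sim N(0, 0.4^2)\) per gene and patient, shared by the patient's
  three samples: this is what makes samples cluster by patient;
* `dispersion_trend = c(a = 1, b = 0.02)`: the standard decreasing
  mean-dispersion shape, ~14% biological CV at high expression;
* library sizes log-uniform in 1.5–3 × 10⁷ (exercises normalization; CPM
  must cancel them exactly, and a test asserts it);
* 35% of genes tumor-vs-normal DE with lfc \(\sim N(0, 1.5^2)\) on both
  tumor samples;
* progressive effects on the PVTT only (the "progressive alteration"
  reading): one block of 15% of genes at |lfc| = 2 in 3 patients and one of
  0.5% in 5 patients, reproducing the observed skew where a few patients
  carry thousands of progressive genes and most carry almost none, plus 20
  recurrent genes planted in 7 patients each with per-gene consistent sign;
* 4% dosage-coupled genes at 0.5 log2/copy with copy states drawn from
  {−1, 0, 1, 2}; 1.2% methylation-silenced genes whose per-tumor promoter
  beta shift (uniform 0.15–0.55) feeds expression at −4 log2 per unit beta —
  silencing of one to two fold-changes over the observed beta range, typical
  of strong promoter hypermethylation.

All three generators (counts, CNV segments, methylation betas) derive
independent sub-streams from one seed, so outputs are byte-identical under a
fixed config and adding one data type never perturbs another. Ground truth is
returned as a table keyed by gene (and patient where applicable); the latent
per-sample copy states and beta shifts travel as attributes so the CNV and
methylation simulators stay consistent with the expression already drawn.

**What the simulator does not emulate** — and therefore what passing tests do
not show about real data: GC/length biases and other count artifacts,
correlated gene modules (genes are independent given the planted structure),
subclonal mixtures, batch effects, outlier samples, and arm-level events
coupled to expression. Recovery rates measured here are upper bounds for real
cohorts.

## Calibration experiments and numerical choices

The null-calibration suite (19 trios × 10,000 genes, no planted effects)
checks that pooled per-patient p-values are uniform within three Monte-Carlo
standard errors at p ∈ {0.01, 0.05, 0.1}. That cohort sets
`patient_effect_sd = 0` and a constant library size: the paired difference
cancels patient effects while the trend includes them, so with patient
effects present the test is conservative *by design* and raw uniformity
cannot (and should not) hold; calibration is meaningful exactly under the
variance model's homogeneity assumptions. Residual NB-log kurtosis leaves the
empirical tail at p < 0.01 about one to two SE above nominal — visible, but
within the tolerance, and it shrinks with depth.

The power suite plants a realized pair difference of exactly
\(3\sqrt{2\sigma^2|\mu}\) (z = 3) for 100 genes in 5 of 19 patients and
requires ≥ 80% recovery at q < 0.1 over 25 replicates of 2,000-gene cohorts
— with a 5% planted fraction the BH threshold sits near q ≈ 0.054, so
recovery is essentially complete; false calls among nulls stay far below the
15% bound. Planting the *expected* shift instead (realized z ~ N(3, 1))
halves recovery by the usual BH fixed-point argument; the realized-difference
construct is the stated contract.

Other numerical decisions: BH ties are broken by stable gene order; d = 0
pairs get z = 0, p = 1 and an NA direction; genes overlapping no CNV segment
are NA-flagged rather than imputed; probes with fewer than 3 complete pairs
are excluded and logged; beta/M conversion uses the logistic link
\(M = \log_2(\beta/(1-\beta))\) so M = 0 is exactly \(\beta = 0.5\);
coordinates are 0-based half-open in BED input, 1-based inclusive in SEG and
probe positions, converted at the I/O boundary.

Problem sizes in the default test run are scaled so the whole suite is a
desk-scale exercise (the 10,000-gene calibration cohort takes ~2 s; the full
suite ~30 s): these are the package's own choices, stated here so that a
reader scaling up to transcriptome-sized cohorts knows the defaults were
validated at these sizes and interpolate linearly in genes × samples.

## Known limitations

* The z-test treats the two pair members as independent given the patient;
  shared library-preparation artifacts within a patient would make the test
  conservative, not liberal, but are not modeled.
* The trend evaluates \(\sigma^2\) at the pair mean \(\mu_{ij}\) (as the
  statistic is defined), not separately per member; with strongly asymmetric
  pairs and a steep trend this is an approximation.
* The permutation FDR conditions on per-patient call counts; it does not
  model correlation between patients' call sets beyond gene identity.
* The cohort z for arm recurrence is a stand-in definition; absolute z
  values are not comparable to segmentation-suite outputs, only the cutoff
  semantics are.
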