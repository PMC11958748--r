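---
title: "Methods: permutation-based empirical t-tests and EASE enrichment"
author: "permDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation-based empirical t-tests and EASE enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permDE)
```

# The problem

Small bulk RNA-seq designs -- two conditions with three biological
replicates each are typical for mouse tissue studies such as brown-fat
(BAT) transcriptome comparisons -- leave too few degrees of freedom for
well-behaved parametric per-gene tests, and too few samples for per-gene
permutation tests: a 3 vs 3 design admits only `choose(6, 3) = 20` distinct
group-label assignments, so no per-gene permutation p-value can ever fall
below 1/20. permDE implements the workflow commonly used in this setting:

1. **Expression filter.** Keep genes with FPKM strictly greater than 1 in
   at least one sample. The filter runs on the raw FPKM scale, before any
   transform, and the strict inequality makes the boundary deterministic.
2. **Transform.** Replace every value by $\log_2(\mathrm{FPKM} + 1)$, which
   maps FPKM 0 to 0 and compresses the right tail.
3. **Quantile normalization.** Classic sort--average--reassign: the $k$-th
   smallest value of each column becomes the mean over columns of the
   $k$-th smallest values, forcing all samples onto one empirical
   distribution.
4. **Empirical t-test.** For gene $g$, the pooled-variance Student
   statistic
   $$t_g = \frac{\bar{x}_{g,\mathrm{treated}} - \bar{x}_{g,\mathrm{control}}}
   {\sqrt{s^2_{p,g}\,(1/n_1 + 1/n_2)}}$$
   is referred not to a Student reference but to an *empirical null*: group
   labels are permuted jointly over all samples $B$ times (group sizes
   preserved), $t$ is recomputed for every gene, and all $|t^*|$ values are
   pooled across genes and permutations into one global null. The
   two-sided, add-one-smoothed empirical p-value is
   $$p_g = \frac{1 + \#\{|t^*| \ge |t_g|\}}{1 + nB}.$$
5. **DEG call.** Benjamini--Hochberg adjustment of the empirical p-values;
   a gene is differentially expressed iff $p^{\mathrm{adj}}_g < 0.05$
   (strict) *and* $|\log_2 \mathrm{FC}_g|$ strictly exceeds a cutoff that is
   either the 95th percentile of all $|\log_2 \mathrm{FC}|$ (data-driven
   "top 5%" mode) or a fixed value, 0.336 by default (about 1.26-fold).
   Here $\log_2 \mathrm{FC}$ is the difference of group means on the
   normalized $\log_2(\mathrm{FPKM}+1)$ scale, so the cutoff lives on the
   same scale as the transform.
6. **Enrichment.** Gene sets from GMT files are tested for
   over-representation of the DEG list with the EASE score: the one-sided
   Fisher exact (hypergeometric upper-tail) p-value recomputed after
   removing one gene from the overlap,
   $$p^{\mathrm{EASE}} = P(X \ge \max(k - 1, 0)), \qquad
     X \sim \mathrm{Hypergeom}(N, m, n),$$
   a jackknife that deflates sets whose significance hinges on a single
   gene. Sets are selected at uncorrected $p^{\mathrm{EASE}} < 0.05$.

# Why a pooled null, and what it costs

Pooling permuted statistics across genes is what rescues the 20-assignment
design: the pooled null has $n \times B$ entries, so p-values down to
$1/(1 + nB)$ are attainable and Benjamini--Hochberg has something to work
with. The cost is that the pooled null estimates the *marginal* null
distribution over genes. Two consequences matter in practice:

* **Validity is kept.** Sampling assignments uniformly *with replacement,
  including the identity* makes the empirical p-value super-uniform under
  the null (the observed statistic is always counted at least once in its
  own reference), the standard argument for never reporting a permutation
  p of zero. Calibration on a global-null simulation is part of the
  acceptance suite: the fraction of genes with $p < \alpha$ tracks
  $\alpha$ within binomial error at $\alpha \in \{0.01, 0.05, 0.10\}$.
* **Power under strong alternatives is structurally limited.** Every
  truly-changed gene contributes its own extreme $|t|$ to the pooled null
  whenever a permutation reproduces the observed grouping (2 of the 20
  assignments in a 3 vs 3 design, so weight 2/20 in expectation). If a
  fraction $\pi$ of genes carries real effects, the $k$-th smallest
  empirical p-value is therefore bounded below by roughly
  $0.1\,k/n$ -- exactly twice the Benjamini--Hochberg boundary
  $0.05\,k/n$. Independently of that, with $n_1 = n_2 = 3$ the statistic
  has only 4 denominator degrees of freedom, and its sampling noise alone
  caps the power of any FDR-controlled call at moderate effect sizes.
  The acceptance suite measures exactly this: on simulations with 10%
  planted genes shifted by 2 log2-units over noise sd 0.5, direction
  accuracy and power monotonicity hold, while absolute sensitivity at
  BH 0.05 remains near zero. This is a property of the method under those
  conditions, reported honestly rather than patched; users who need
  discovery power at $n = 3$ should treat the empirical test as a ranking
  procedure (or use the fixed fold-change mode with a relaxed alpha) and
  validate candidates independently.

The percentile fold-change mode has a related interaction worth knowing:
if 10% of genes are truly changed, the 95th percentile of $|\log_2 FC|$
falls *inside* the changed population, so the cutoff by construction
removes about half of the true positives. The fixed mode (0.336) does not
have this property.

# The synthetic-data generator

`simulate_fpkm()` emulates the study design the analysis assumes, on the
$\log_2(\mathrm{FPKM}+1)$ scale so that the preprocessing transform inverts
the generator exactly:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 5000 | genes (a few thousand expressed genes, desk scale) |
| `n_per_group` | 3 | replicates per condition |
| `frac_de` | 0.1 | fraction of genes with a planted shift |
| `effect_size_log2` | 2 | magnitude of the shift, random sign per gene |
| `baseline_mean_log2` | 6 | mean of per-gene baselines (FPKM around 64) |
| `baseline_sd_log2` | 1.2 | spread of baselines across genes |
| `noise_sd_log2` | 0.5 | per-sample noise sd |
| `frac_silent` | 0.1 | genes forced below the expression filter |

Per gene, a baseline $b \sim N(\mu_b, \sigma_b)$ truncated at 0 (truncation
rather than resampling keeps the draw order, and hence determinism,
trivial); each sample value is $b + \delta + \varepsilon$ with
$\varepsilon \sim N(0, \sigma)$ and $\delta = \pm$`effect_size_log2` in the
treated group of DE genes (signs are Rademacher, so both up- and
downregulation occur); FPKM is $2^x - 1$ clipped at 0. Silent genes draw
all FPKM from $U[0, 0.5]$, guaranteeing removal by the FPKM > 1 filter.
Baseline defaults put essentially no non-silent gene below the filter
(probability $< 10^{-4}$ per run at 5000 genes), so "silent" and
"filtered" coincide by design. One integer seed drives a single documented
draw order; the same seed reproduces every byte.

What the generator does *not* emulate: sequencing-depth count noise
(negative binomial dispersion), gene--gene correlation, length biases, and
the heavy right tail of real FPKM distributions. Passing tests therefore
demonstrate the statistical machinery is correct and calibrated under the
stated model, not that real BAT data would behave identically.
`simulate_gene_sets()` plants enrichment by drawing a configurable
fraction (default 0.8) of designated sets' members from the DE genes,
giving ground truth for the enrichment stage.

# Numerical and design choices

* **Pooled-variance t, not Welch.** The default for $n = 3$ designs, where
  per-group variances are hopeless to estimate separately; Welch is a
  config switch (`welch = TRUE`).
* **Variance floor** (`1e-8`): quantile normalization can create exactly
  tied rows; flooring the pooled variance keeps $t$ finite and
  deterministic ($t = 0$ for two identical constant groups).
* **Tie handling in quantile normalization**: ties within a column receive
  the *mean of the reference values at the tied ranks*. This is stated
  explicitly because conventions differ between implementations (rank
  interpolation at the average tied rank gives different values for tie
  groups of three or more); FPKM ties, zeros especially, are common.
* **Benjamini--Hochberg on empirical p-values** is the adjustment; a
  direct permutation FDR (mean null exceedances over observed exceedances,
  monotonized) is available as `adjust_method = "perm_fdr"` for
  sensitivity analysis.
* **"Top 5%" fold-change cutoff** is interpreted as the 95th percentile of
  $|\log_2 FC|$ (type-7 linear interpolation): a stringency filter keeping
  the largest 5% of absolute fold changes. A fixed mode (0.336) is
  provided for reproducing analyses that quote that threshold verbatim.
* **Enrichment universe** is the set of expressed (filtered) genes -- the
  genes the DE stage actually scored -- rather than a whole-genome
  background; set members outside the universe are ignored.
* **Hypergeometric tails** are computed by `stats::phyper()`, which works
  in log space; the test suite verifies them against explicit summation of
  the mass function over every valid count configuration up to a universe
  of 200 (relative error below 1e-9).
* **Exhaustive mode as oracle.** `permutation_scheme = "exhaustive"`
  enumerates all distinct assignments and is used to validate the sampled
  mode: on 200-gene instances, sampled p-values at $B = 2000$ agree with
  the exhaustive ones within 0.02.
* **Canonical sample order.** `call_degs()` orders samples by (group,
  sample id) before drawing permutations, so results are invariant to the
  column order of the input for a fixed seed.
* **Strict thresholds.** DEG calls use $p^{\mathrm{adj}} < 0.05$ and
  $|\log_2 FC| >$ cutoff, both strict.

# Problem sizes used by the test and acceptance suites

Calibration and recovery checks run at 5000 genes with $B = 1000$
permutations (a few seconds each), oracle-equivalence at 200 genes with
$B = 2000$, normalization properties on 100 random small matrices, and the
EASE scan over all count vectors with universes up to 200. These sizes were
chosen to make the statistical assertions sharp (binomial error bands of a
few tenths of a percent) while keeping a full run at desk scale.

# Known limitations

* Two-group designs only; no covariates, pairing, or count models -- FPKM
  is the contract boundary, downstream of transcript quantification.
* The pooled null assumes genes are exchangeable under permutation;
  strongly correlated gene blocks make the calibration band approximate.
* At $n = 3$ per group the workflow has ranking power but little absolute
  discovery power at FDR 0.05 (see above); this is inherent, not an
  implementation artifact.
* The enrichment stage tests over-representation only (no
  pathway-topology, no ID mapping); multiple-testing correction across
  sets is off by default to mirror the uncorrected EASE selection
  convention, and available via `adjust = TRUE`.
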