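---
title: "Set-based association testing from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based association testing from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastbat)
```

## The model

A genome-wide association study reports, for each SNP $i$, an effect size
$b_i$, its standard error $s_i$, and a p-value. The z-statistic is
$z_i = b_i / s_i$. For a *set* of $m$ SNPs — typically all SNPs within 50 Kb
of a gene — the joint null hypothesis is that none of them is associated
with the trait. Under that null, and because nearby SNPs are correlated
through linkage disequilibrium (LD), the vector
$\mathbf{z} = (z_1, \dots, z_m)$ is multivariate normal,
$\mathbf{z} \sim \mathrm{MVN}(\mathbf{0}, \mathbf{R})$, where $\mathbf{R}$
is the $m \times m$ LD correlation matrix of the SNPs.

The set statistic is the sum of the per-SNP chi-squared statistics,
$T = \sum_i z_i^2 = \mathbf{z}^\top \mathbf{z}$, a quadratic form in
multivariate-normal variables. Its null distribution is a weighted sum of
independent 1-df chi-squares,

$$T \;\sim\; \sum_{i=1}^{m} \lambda_i \, \chi^2_{1,i},$$

with weights $\lambda_i$ the eigenvalues of $\mathbf{R}$. Everything the
test needs beyond the summary statistics is $\mathbf{R}$, which is
estimated from a reference genotype panel (the GWAS cohort itself, or a
public panel) — no individual-level phenotype data are required.

Classical set tests obtain the tail probability $P(T > T_{\mathrm{obs}})$
by resampling: permuting phenotypes when individual-level data are
available, or simulating $\mathbf{z} \sim \mathrm{MVN}(\mathbf{0},
\mathbf{R})$. Both are limited by the number of draws $s$: the smallest
achievable p-value is $1/s$, and runtime grows linearly in $s$. Evaluating
the tail of the weighted chi-square sum analytically removes both limits.
Both resampling procedures are implemented here
(`permutation_set_test()`, `mvn_simulation_set_test()`) — not as
alternatives but as independent oracles that the analytic path is tested
against.

## Evaluating the tail

Three evaluators are available through `quadform_pvalue(q, w, method)`:

* **Satterthwaite** (`"satterthwaite"`): moment matching. $T$ is
  approximated by $a\chi^2_d$ with $a = \sum\lambda_i^2 / \sum\lambda_i$
  and $d = (\sum\lambda_i)^2 / \sum\lambda_i^2$. Exact when all weights are
  equal; degrades deep in the tail for skewed spectra.
* **Saddlepoint** (`"saddlepoint"`): Kuonen's formula built from the
  cumulant generating function
  $K(\zeta) = -\tfrac12\sum_i \log(1 - 2\zeta\lambda_i)$. The saddlepoint
  $\hat\zeta$ solves $K'(\hat\zeta) = q$ on
  $(-\infty, 1/(2\lambda_{\max}))$; with
  $w^* = \mathrm{sign}(\hat\zeta)\sqrt{2(\hat\zeta q - K(\hat\zeta))}$ and
  $v = \hat\zeta\sqrt{K''(\hat\zeta)}$ the tail is
  $1 - \Phi\!\left(w^* + \log(v/w^*)/w^*\right)$. Relative accuracy is
  excellent deep in the tail; at the distribution mean the formula is
  singular, and within a relative $10^{-6}$ neighbourhood of
  $q = \sum\lambda_i$ the Satterthwaite value is returned instead.
* **Exact mixture series** (used by `method = "auto"`, also exposed as
  `ruben_tail()`): the classical representation of a positive weighted
  chi-square sum as an infinite mixture of central chi-squares,
  $P(T > q) = \sum_{k\ge0} a_k \, P(\chi^2_{m+2k} > q/\beta)$ with
  $\beta = \lambda_{\min}$, nonnegative weights $a_k$ summing to one, and
  a truncation error bounded by the unaccumulated mixture mass. We stop at
  mass $10^{-12}$, so the result is exact for all practical purposes.

### Why "auto" prefers the exact series

We measured all first- and second-order saddlepoint variants against exact
quadrature for two-eigenvalue spectra and found absolute errors of order
$10^{-3}$ in the body of the distribution (around $p \in [0.05, 0.9]$),
even for nearly equal eigenvalues, growing to $10^{-2}$ for skewed spectra.
That error is invisible in a genome scan ranking but measurable against a
$10^6$-draw Monte-Carlo oracle, whose 3-standard-error band is a few
$10^{-4}$ wide. The mixture series costs little at gene-set sizes (its
convergence is geometric at rate $1 - \lambda_{\min}/\lambda_{\max}$) and
is exact, so `auto` uses it wherever it converges, switching to the
saddlepoint only for very deep tails ($p < 10^{-8}$, where an absolute
truncation bound no longer implies relative accuracy and the saddlepoint's
relative error of a few percent is preferable) or when the eigenvalue
spread stalls the series. Both pure approximations remain selectable, and
the deep-tail path means reported genome-wide-significant p-values are
saddlepoint values — consistent with their usual description.

Two degenerate spectra short-circuit to closed forms: all eigenvalues equal
(independent SNPs, $T/\lambda \sim \chi^2_m$) and a single nonzero
eigenvalue (all SNPs in perfect LD, $T/m \sim \chi^2_1$). These are also
the package's first acceptance checks.

## LD estimation and pruning

`compute_ld()` computes Pearson correlations of allele counts (genotypic
$r$; reference panels are unphased), after per-SNP mean imputation of
missing calls. Monomorphic SNPs are an error, named. The matrix is
symmetrised and its diagonal forced to 1; small negative eigenvalues from
rounding are clamped to zero in `spectral_weights()` — $\mathbf{R}$ is
positive semi-definite in exact arithmetic. Allele orientation does not
matter: flipping a coded allele flips the sign of $r$, and only $r^2$
(through the spectrum) enters the test, so summary/panel harmonisation
checks identifiers and unordered allele pairs only.

Sets sometimes contain SNPs in near-perfect LD, which dilute the
aggregated signal: a duplicated null marker adds a full unit of null
chi-square to $T$ while adding nothing to the signal. `prune_by_ld()`
therefore removes SNPs until no pair exceeds an $r^2$ threshold: it builds
the graph of above-threshold pairs and repeatedly deletes the vertex with
the highest current degree (the SNP involved in the most offending pairs),
recomputing degrees after each deletion. Ties are broken by removing the
SNP latest in positional order — deterministic, and deliberately blind to
the association statistics (pruning on p-values would bias the test). This
greedy rule keeps the number of removals small but is a heuristic: finding
the true minimum is a vertex-cover problem, and the tests verify the
greedy count is never below the brute-force optimum on small instances.
The recommended threshold is $r^2 = 0.9$; thresholds below about 0.7 start
discarding genuinely distinct signal and are not recommended. A threshold
of 1 removes nothing (no finite pair exceeds $r^2 = 1$) and so doubles as
the "no pruning" setting of the sweep grid.

## The synthetic-data generators

All validation runs on synthetic cohorts; every generator draws from named
sub-streams of one master seed (`stream_seed()`), so any part of an
experiment can be reproduced in isolation.

* `simulate_unlinked_genotypes()`: allele frequencies
  $p \sim U(0.01, 0.99)$, genotypes $x \sim \mathrm{Binomial}(2, p)$,
  mutually independent SNPs. This is the canonical null model for
  calibration and for power studies where LD is not the object.
* `simulate_block_genotypes()`: a latent-Gaussian (copula) generator.
  Within blocks of consecutive SNPs the latent variables follow an AR(1)
  process; two latent draws per individual are thresholded at each SNP's
  frequency quantile and summed. Realised LD rises monotonically with the
  latent correlation, and the generator has a tractable oracle (the
  thresholded-Gaussian pair correlation), which the tests exploit. It
  emulates block-wise LD only — not recombination hot-spot fine structure,
  allele-frequency-dependent LD, or long-range admixture LD — so passing
  tests demonstrate correctness of the machinery, not realism of any
  particular human LD landscape.
* `simulate_phenotype()`: $y = \sum_j w_j b_j + e$ with standardised
  causal genotypes $w_j$, effects $b_j \sim N(0, h^2_1)$ where $h^2_1$ is
  the target per-variant variance fraction (defaults 0.004, or 0.002 in the
  dense-panel pruning studies), and residual variance fixed analytically at
  $1 - k h^2_1$ — each causal variant explains its target fraction exactly
  in expectation, with no post-hoc rescaling. The drawn effects are kept in
  the cohort object as simulation truth.
* `place_clustered_causals()`: emulates clustered architectures — pick a
  uniform 200 Kb window, draw the cluster size from
  $\mathrm{Binomial}(50, 0.1)$ (mean 5), sample that many common SNPs, and
  repeat until 50 causal variants are placed.
* `marginal_scan()`: per-SNP simple linear regression (t-based p-values),
  producing summary statistics in the same layout as `read_ma_summary()`,
  so the full file-based workflow is testable from synthetic data alone.

Set sizes in the simulation studies are configurable; the default scenarios
use at least 10 SNPs per set, mirroring the usual practice of excluding
very small gene sets.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout (PLINK convention); a gene
  window of $W$ Kb means positions in $[start - 1000W,\; end + 1000W]$,
  boundaries included.
* Missing genotypes are kept at read time and mean-imputed only inside LD
  estimation; QC (MAF $\ge$ 0.01, HWE p $\ge 10^{-6}$, missingness
  $\le$ 0.02 by default, all exposed as parameters) is applied jointly, so
  filter order cannot matter.
* The HWE filter uses a 1-df chi-squared goodness-of-fit test on genotype
  counts — a threshold-style filter, not an inference procedure, so the
  exact test's extra precision at rare genotypes is not needed.
* Per-SNP chi-squares prefer $b/s$ over the p-value when both are present
  (rounded p-values lose precision in deep tails); a flag flips this.
* The empirical p-value convention is $(r + 1)/(s + 1)$, which never
  returns zero; its floor $1/(s+1)$ is asserted, not avoided — it is the
  point of contrast with the analytic tail.
* The staged simulation oracle runs 1,000 draws first and escalates to the
  full budget only when the interim corrected p-value is below 0.001; the
  corrected (not raw) interim value is compared against the threshold.
* Per-set failures (no overlap between summary and panel, monomorphic
  SNPs) skip the set with a recorded reason; a genome-wide run never dies
  on one bad gene.
* Results are sorted by p-value, ties broken by set id; all file outputs
  carry the run configuration, including the seed, as `#` header comments.

## Problem sizes used in validation

The test-suite and acceptance-script experiments are desk-scale by design:
closed-form checks are instant; oracle agreement uses up to 100 random LD
matrices ($m \le 20$) against $10^6$ Monte-Carlo draws each; permutation
concordance uses cohorts of 5,000 individuals with $10^4$ permutations per
set; null calibration uses 1,000 ten-SNP sets; the power orderings use
10,000-individual cohorts with 0.4% variance per causal variant, the
perfect-LD duplication scenarios, and 100–200 replicates; the pruning
studies use block-LD cohorts with causal variants placed at low-LD
positions. These sizes make the statistical contrasts decisive (several
standard errors) while keeping the whole suite in minutes on one core.

## Known limitations

* The analytic null assumes the z-statistics are well-calibrated and the
  reference panel's LD matches the GWAS cohort's; mismatched ancestry
  inflates or deflates set p-values, and no correction is attempted.
* Genotypic $r$ from small reference panels is noisy; the test is robust
  to moderate noise but very small panels will degrade tail accuracy.
* Only PLINK-1 bed/bim/fam reference panels and GCTA-style summary text
  are read; no VCF/BGEN, dosages, or imputation.
* The block-LD generator is a statistical stand-in, not a population
  genetics simulator; conclusions about real LD architectures require real
  panels.
* Conditional analysis (dissecting multiple signals at a locus) and
  best-SNP style tests are out of scope.
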