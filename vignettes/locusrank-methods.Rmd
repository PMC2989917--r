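---
title: "Methods: locus-size-corrected gene ranking, gene-set enrichment, and replication statistics"
author: "locusrank maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus-size-corrected gene ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusrank)
```

# The model and its assumptions

## Why min-P gene ranks are biased

A gene-based GWAS summary assigns each SNP to every gene locus whose
±10 kb window (relative to the first and last exon, 1-based inclusive
coordinates, strand ignored) contains it, and summarises the gene by the
smallest per-SNP p-value.  Under the global null the minimum of $k$
independent uniform p-values has expectation $1/(k+1)$, so genes with many
SNPs — equivalently, long genes — drift to the top of the rank by chance.
`snp_count_bias()` measures this as the Spearman correlation between
per-gene SNP count and $-\log_{10} p$, with a permutation p-value obtained
by shuffling the SNP counts against the evidence column (the directional
one-sided alternative is the default, because the bias can only inflate
SNP-rich genes).

## The permutation correction

Each SNP is tested under the additive model with an age-adjusted partial
correlation: status and dose are each residualised on age by least squares
with intercept, the residuals are correlated, and
$t = r\sqrt{(n-3)/(1-r^2)}$ with $n-3$ degrees of freedom.  The gene-level
statistic is $M_g = \max_{j \in g} |t_j|$.

Significance of $M_g$ is calibrated by case-control permutations: one set
of $B$ permuted status vectors is drawn and shared by all genes and SNPs,
preserving the correlation structure between SNPs; ages stay attached to
their subjects.  The adjusted p-value is the add-one estimator
$(\#\{M_g^{(b)} \ge M_g\} + 1)/(B+1)$, which is never zero and lies in
$[1/(B+1), 1]$.  A gene with many SNPs has a larger null maximum, so its
observed maximum is judged against a correspondingly harder reference —
this is what removes the size bias.

Implementation notes:

* All per-permutation statistics are computed by one matrix product per
  block of permutations (both dose matrix and permuted status vectors are
  residualised against $[1, \text{age}]$ once; $|t|$ is monotone in $|r|$
  at fixed $n$, so exceedances are counted on the correlation scale).  Null
  maxima are never stored; per-gene exceedance counters bound memory, and a
  `block_size` knob bounds the working set.
* Exceedance uses a $10^{-9}$ tolerance on the correlation scale so that
  ties — including the identity labeling, which is always among the
  exhaustive labelings — count as exceedances.  Without it, floating-point
  jitter between the scalar and matrix code paths can drop an exact tie.
* `exhaustive = TRUE` enumerates all $\binom{n}{n_\text{case}}$ labelings
  (capped at $2\times10^5$) and returns the exact probability
  $\#\{M^{(b)} \ge M_g\}/\#\text{labelings}$ without the add-one term.
* Missing doses are mean-imputed inside the permutation engine (with a
  warning); exact pairwise deletion per SNP per permutation is incompatible
  with the shared-null matrix computation.  Single-SNP testing
  (`snp_association()`) uses true pairwise deletion.
* Status is permuted unrestricted by default, which matches the literal
  description of case-control permutation but breaks any age–status
  association in the null; `stratify_age = TRUE` permutes within the age
  bands instead.  The unrestricted default is kept because the correction
  targets the size bias, which is invariant to this choice under the null.

An open question in the source analysis is whether the final rank re-orders
genes by the adjusted p of the max-$|t|$ or by an adjusted genotypic-test
p.  This package ranks by the adjusted max-$|t|$ p (ties broken by larger
$M_g$, then gene id), following the methods description of the correction
itself.

## Gene-set enrichment

`enrichment_score()` is the weighted Kolmogorov–Smirnov running sum:
walking the ranked list, members add $|s_i|^p / N_R$ (with
$N_R = \sum_{\text{members}} |s_i|^p$) and non-members subtract
$1/(N - N_H)$; the ES is the signed maximal deviation.  With $p = 0$ the
statistic reduces to the classical unweighted KS deviation and the walk
ends exactly at zero (a unit-test identity).  The default score is
$-\log_{10} p_\text{adj}$.

The null for `set_significance()` permutes **gene labels** (random sets of
identical size), not phenotypes: the module consumes a pre-ranked list, and
a phenotype null is unavailable without re-running the genome-wide
permutation per gene set.  This is a documented divergence from the
original GSEA tool's default; it is shared by every pre-ranked GSEA
application.  One null panel is drawn per distinct set size and shared by
all sets of that size, so identical memberships give identical results
under one seed.  NES divides ES by the mean same-sign null ES; the nominal
p is the add-one same-sign tail proportion; FDR q is the GSEA
ratio-of-tails on the pooled null NES.  `group_fdr()` applies
Benjamini–Hochberg within user-defined hypothesis groups, reflecting the
design in which prognosis, treatment-response and somatic-alteration set
families are tested as separate hypotheses.  Set-size bounds default to
[5, 5000].

## Replication-study statistics

All estimators work from 2×3 case-control genotype count tables:

* **HWE**: 1-df chi-square against expected counts from the estimated
  allele frequency, or the exact conditional test (probability-ordered
  enumeration of heterozygote counts given the minor-allele count); `auto`
  uses the exact test for totals ≤ 500.  Monomorphic input returns p = 1
  with a flag.  Note the exact test is intrinsically conservative and
  discrete: its null p-values are *not* uniform, and it can differ from
  the chi-square p by more than 0.1 at a few hundred subjects; the test
  suite asserts the realistic envelope rather than pointwise agreement.
* **Per-genotype ORs**: cross-products versus the common-homozygote
  reference with Wald CIs, no continuity correction (the printed intervals
  match the uncorrected formula).  Zero cells are flagged, not corrected.
* **Trend/dominant/recessive**: the trend OR is fit by logistic regression
  on dose with frequency weights (not the allele-counting shortcut);
  dominant/recessive collapse to 2×2 cross-products.  The default p-value
  is the likelihood-ratio test: on the early-onset *CDKL2* table the LRT
  gives 0.0436 (prints as 0.044) while Wald gives 0.049 and Pearson 0.040,
  so only the LRT reproduces the published value — the acceptance suite
  checks this discrimination.
* **Age adjustment**: unconditional logistic regression with stratum
  indicators over the bands 20–46, 46–56, 56–66, 66–91 years (similar
  stratum sizes in the emulated study), or Mantel–Haenszel with the
  Robins–Breslow–Greenland CI for collapsed models.  Conditional logistic
  regression is out of scope.
* **Permutation trend p**: label permutation of the (optionally
  stratum-summed) Cochran–Armitage score statistic, two-sided, add-one
  estimator; exhaustive enumeration available for toy data.
* **Subtype interaction**: subtype-specific trend ORs against the shared
  controls; the default p is a Wald z on the difference of log-ORs with
  summed variances, the alternative a case-only logistic trend of subtype
  on dose.  Neither is claimed to be the published test (the published
  interaction p-values are age-adjusted and not reproducible from counts
  alone); both are provided.

# The synthetic cohort: what it emulates and what it does not

The generator's defaults are the stated world of the analysis being
emulated, chosen once:

| parameter | default | rationale |
|---|---|---|
| extension distribution | log-normal, meanlog 10.317, sdlog 1.249 | solves the moment equations for mean 66 kb, σ 128 kb — the genome-wide moments of annotated loci |
| SNP density | 0.5 / kb, Poisson, min 1 | SNP count proportional to extension at roughly array density |
| MAF | Uniform(0.05, 0.5) | common variants, post-QC |
| genotypes | Binomial(2, MAF) | Hardy–Weinberg, no LD |
| age | Normal(55, 12) truncated to [20, 91] | the control age range and approximate centre of the emulated cohorts |
| baseline log-odds | 0 | case-control balance, not population prevalence |
| causal effects | none by default | the source analysis does not state how many causal loci underlie its data; effect sizes are per-test choices |

Genes are laid end-to-end with 50 kb gaps on up to 23 synthetic
chromosomes, so gene bodies and ±10 kb windows never overlap.  One master
seed feeds per-operation streams (annotation, genotypes, phenotypes), so
each stage is independently reproducible.

With `age_maf_slope` non-zero, ages are drawn at genotype time and the
logit allele frequency varies linearly with age, making age a genuine
confounder — the configuration used to test that stratified estimates beat
crude ones.  With a `subtype_spec`, every subject carries a latent tumour
subtype drawn from the specified weights, the subtype's per-allele log-ORs
drive the case model, and the label is observed for cases only.  When a
subtype specification is present it replaces the plain `causal` effects
rather than adding to them.

Not emulated: linkage disequilibrium (SNPs are independent within genes;
an adjacent-SNP correlation would sharpen the shared-permutation null but
the emulated analysis is silent on LD), population structure, imputation
uncertainty, X-chromosome dosage, genotyping error.  A green test on this
generator therefore establishes correctness of the statistical machinery
under HWE and independence — not robustness to LD or stratification.

# Numerical choices and degenerate inputs

* Partial correlations with $|r| \ge 1 - 10^{-12}$ return $t = \pm\infty$,
  p = 0, flagged `perfect_correlation`; constant doses return NA statistics
  flagged `constant_dose` and are skipped when taking gene maxima.
* Constant age falls back to the unadjusted correlation with $n-2$ df,
  flagged.
* No continuity corrections anywhere (chi-square, trend, ORs); zero cells
  yield flagged NAs rather than Haldane–Anscombe corrections, because the
  published intervals match the uncorrected formulas.
* p-value ties in ranking are broken lexicographically by gene id
  (stable, deterministic); the adjusted rank breaks p ties by larger
  $M_g$ first.
* The permutation workload guard errors when $B \times n_\text{SNPs}$
  exceeds `max_cells` (default $2\times10^9$) instead of thrashing.

# What the tests establish

Every operation is checked against an independent oracle: brute-force
double loops (SNP↔gene assignment, per-gene minima/maxima), explicit
residual regressions (partial t), the weighted-proportion formula
(Cochran–Armitage), textbook Mantel–Haenszel and BH computations,
step-by-step running sums (ES), enumeration oracles (exact HWE, exhaustive
permutations), and calibration/power simulations (uniform null p-values,
CI coverage of injected odds ratios, bias removal on null cohorts).  The
acceptance suite reproduces the published crude table statistics to
printed precision and verifies the LRT/Wald discrimination.  Published
quantities that depend on access-controlled subject-level data
(age-adjusted ORs, the original GWAS enrichment p-values) are deliberately
not asserted; the corresponding machinery is exercised on synthetic
cohorts instead.

# Known limitations

* The gene-label null for pre-ranked enrichment understates
  between-gene correlation relative to a phenotype null.
* Mean-imputation of missing doses inside the permutation engine is an
  approximation; heavily missing SNPs should be filtered beforehand.
* The exact HWE p is conservative by construction; use the chi-square
  variant when uniformity matters (e.g. QQ plots).
* Conditional logistic regression and LD-aware nulls are out of scope.
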