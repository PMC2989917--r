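# locusrank

Gene-level ranking of genome-wide association study (GWAS) results that
corrects the locus-size bias, GSEA-style enrichment of somatic gene sets on
the corrected rank, and the complete statistical toolbox of a case-control
replication study — plus a synthetic-cohort generator so the whole chain is
testable without access-controlled genotype data.

## The problem

Summarising a GWAS at the gene level by the smallest per-SNP p-value inside
a ±10 kb window around each locus ("min-P") is anti-conservative for large
genes: the longer a locus, the more SNPs it contains, and the smaller its
minimum p becomes by chance alone.  Since many cancer genes span large
genomic regions, any enrichment analysis run on an unadjusted min-P rank is
confounded by locus size.

`locusrank` implements the permutation correction: each gene *g* is
summarised by

&nbsp;&nbsp;&nbsp;&nbsp;*M<sub>g</sub>* = max<sub>j ∈ g</sub> |t<sub>j</sub>|,

where *t<sub>j</sub>* is the t statistic of the age-adjusted partial
correlation between genotype dose (0/1/2, additive model) and case-control
status at SNP *j*:
*r* = cor(resid(status ~ age), resid(dose ~ age)),
*t* = *r*·√((n−3)/(1−r²)).  A single set of *B* case-control label
permutations (default 10,000) is shared across all SNPs and genes; each
permutation yields a null *M<sub>g</sub>* for every gene, and the adjusted
p-value is the add-one estimator (exceedances+1)/(B+1).  Because a SNP-rich
gene also has a larger null maximum, the adjusted rank is free of the size
bias — `snp_count_bias()` quantifies this as the Spearman correlation
between per-gene SNP count and −log₁₀ p.

Downstream, `set_significance()` runs the weighted Kolmogorov–Smirnov
(GSEA) statistic on the adjusted rank with a random-gene-set null, and the
`replication_tables` functions reproduce every statistic of a 2×3
case-control genotype table study: Hardy–Weinberg tests (chi-square and
exact), per-genotype/trend/dominant/recessive odds ratios with Wald CIs and
likelihood-ratio p-values, Mantel–Haenszel and age-stratum-adjusted
estimates, permutation trend p-values, and tumour-subtype (e.g. ERα status)
interaction tests.

## Worked example

```r
library(locusrank)

cfg <- sim_config(n_genes = 300, n_subjects = 800, seed = 42,
                  causal = c(g0007 = log(1.8)))      # one real risk locus
cohort <- simulate_cohort(cfg)

lm    <- assign_snps_to_genes(cohort$study$map, cohort$annotation)
assoc <- snp_association(cohort$study, tests = c("partial_t", "genotypic"))

# unadjusted min-P rank: strongly size-biased
unadj <- min_p_rank(lm, data.frame(snp_id = assoc$snp_id, p = assoc$p_genotypic))
snp_count_bias(unadj, seed = 1)
#> <bias_report> Spearman rho = 0.754 (perm p = 0.001, B = 999)
#>   mean SNPs/gene: top decile 123.8 vs overall 38.0

# permutation-adjusted rank: bias gone, causal gene on top
adj <- permutation_adjusted_p(cohort$study, lm, B = 2000, seed = 42)
head(adj$ranked, 3)
#>   gene_id      p_value statistic n_snps best_snp_id
#> 1   g0007 0.0004997501  6.243377      7     s000193
#> 2   g0057 0.0024987506  3.785819     12     s001784
#> 3   g0142 0.0084957521  3.681349     37     s004495
snp_count_bias(adj$ranked, seed = 1)
#> <bias_report> Spearman rho = 0.050 (perm p = 0.214, B = 999)
#>   mean SNPs/gene: top decile 29.8 vs overall 38.0
```

The injected causal gene `g0007` ranks first with the smallest attainable
adjusted p (1/2001 ≈ 5·10⁻⁴), the top decile of the unadjusted rank is
dominated by SNP-rich genes (124 vs 38 SNPs on average), and the adjusted
rank shows no residual correlation between SNP count and significance.

Replication statistics work straight from printed count tables:

```r
tab <- count_table("rs6852678", controls = c(39, 28, 9), cases = c(62, 54, 5))
model_or(tab, "recessive")
#>       model  or_point   ci_low   ci_high    p_value p_method flag
#> 1 recessive 0.3208812 0.103259 0.9971504 0.04364846      lrt <NA>
```

i.e. recessive OR 0.32, 95% CI 0.10–1.00, P = 0.044 — the likelihood-ratio
p-value; a Wald test on the same table gives 0.049, which is why the
package defaults to the LRT.

## Command line

A thin CLI over the same functions ships in `inst/cli/locusrank.R` with
subcommands `simulate`, `map`, `assoc`, `rank`, `adjust`, `bias-report`,
`gsea` and `replicate`.
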