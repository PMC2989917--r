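Package: locusrank
Title: Locus-Size-Aware Gene Ranking of GWAS Results with Somatic
    Gene-Set Enrichment and Replication-Study Statistics
Version: 0.1.0
Authors@R: person("locusrank", "Maintainers", email = "maintainers@locusrank.org",
    role = c("aut", "cre"))
Description: Gene-level ranking of genome-wide association results that
    corrects the bias introduced by locus size: SNPs are assigned to gene
    loci within a +/-10 kb window, each gene is summarised by the maximum
    absolute age-adjusted partial-correlation t statistic over its SNPs,
    and significance is calibrated by case-control permutations so that
    SNP-rich loci are no longer favoured.  Weighted Kolmogorov-Smirnov
    (GSEA-style) enrichment of somatic gene sets can then be run on the
    adjusted rank.  Also provides the replication-study toolbox for 2x3
    case-control genotype tables (Hardy-Weinberg tests, per-genotype,
    trend, dominant and recessive odds ratios with Wald intervals and
    likelihood-ratio p-values, Mantel-Haenszel and age-stratum-adjusted
    estimates, permutation trend p-values, and tumour-subtype interaction
    tests) and a synthetic-cohort generator so the whole chain is testable
    without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
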