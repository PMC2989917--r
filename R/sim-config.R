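#' Simulation configuration for a synthetic case-control cohort
#'
#' Bundles and validates every knob of the synthetic-cohort generator.  The
#' defaults describe a genome whose gene loci have a strongly right-skewed
#' length distribution (log-normal with natural-scale mean 66 kb and standard
#' deviation 128 kb, the genome-wide moments of annotated human genes), SNP
#' counts proportional to locus extension at one SNP per 2 kb, Hardy-Weinberg
#' genotypes with minor allele frequency uniform on \[0.05, 0.5\], and a
#' case-control sample whose disease status follows an additive log-odds
#' model with an age covariate.
#'
#' @param n_genes number of gene loci to simulate.
#' @param extension_log_mean,extension_log_sd log-scale mean and sd of the
#'   locus extension (bp).  The defaults solve the log-normal moment
#'   equations for mean 66 kb and sd 128 kb on the natural scale.
#' @param snp_per_kb expected typed SNPs per kb of extension (Poisson rate;
#'   every locus keeps at least one SNP).
#' @param maf_min,maf_max bounds of the uniform minor-allele-frequency
#'   distribution; must satisfy `0 < maf_min <= maf_max < 0.5` (0.5 allowed
#'   as a degenerate symmetric case).
#' @param n_subjects number of subjects.
#' @param causal named numeric vector of per-allele log odds ratios, named by
#'   causal gene id (one causal SNP is picked per causal gene), or `NULL`.
#' @param age_mean,age_sd age distribution (years); draws are truncated to
#'   \[20, 91\], the control age range of the emulated replication study.
#' @param age_log_or per-year log odds ratio of age (centred at `age_mean`)
#'   on case status.
#' @param age_maf_slope per-year slope on the logit allele frequency.  Zero
#'   (default) keeps genotype independent of age; a non-zero value makes age
#'   a genuine confounder, which is what the stratified-adjustment tests
#'   need.
#' @param subtype_spec `NULL`, or a list with elements `weights` (named
#'   probabilities of the latent tumour subtypes) and `log_or` (a list, one
#'   named numeric vector of per-allele log ORs per subtype).  When present,
#'   a latent subtype is drawn per subject and that subtype's effects drive
#'   the case model; the label is retained for cases only.
#' @param baseline_log_odds intercept of the case model at mean age and zero
#'   dose.
#' @param seed integer master seed; every generator operation derives its own
#'   stream from it so stages are independently reproducible.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 50, n_subjects = 200, seed = 7)
#' cfg$extension_log_sd
#' @export
sim_config <- function(n_genes = 1000,
                       extension_log_mean = 10.317055,
                       extension_log_sd = 1.249284,
                       snp_per_kb = 0.5,
                       maf_min = 0.05,
                       maf_max = 0.5,
                       n_subjects = 1000,
                       causal = NULL,
                       age_mean = 55,
                       age_sd = 12,
                       age_log_or = 0,
                       age_maf_slope = 0,
                       subtype_spec = NULL,
                       baseline_log_odds = 0,
                       seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1)
    .stopf("invalid config: n_genes must be a positive count")
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 || n_subjects < 1)
    .stopf("invalid config: n_subjects must be a positive count")
  if (extension_log_sd < 0) .stopf("invalid config: extension_log_sd < 0")
  if (snp_per_kb < 0) .stopf("invalid config: snp_per_kb < 0")
  if (!(maf_min > 0 && maf_min <= maf_max && maf_max <= 0.5))
    .stopf("invalid config: need 0 < maf_min <= maf_max <= 0.5")
  if (age_sd < 0) .stopf("invalid config: age_sd < 0")
  if (!is.null(causal)) {
    if (is.null(names(causal)) || any(names(causal) == "") ||
        !is.numeric(causal))
      .stopf("invalid config: causal must be a named numeric vector of log ORs")
  }
  if (!is.null(subtype_spec)) {
    if (!is.list(subtype_spec) ||
        !all(c("weights", "log_or") %in% names(subtype_spec)))
      .stopf("invalid config: subtype_spec needs $weights and $log_or")
    w <- subtype_spec$weights
    if (is.null(names(w)) || any(w < 0) || sum(w) <= 0)
      .stopf("invalid config: subtype_spec$weights must be named, non-negative")
    if (!all(names(subtype_spec$log_or) %in% names(w)))
      .stopf("invalid config: subtype_spec$log_or names must match weights")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) .stopf("invalid config: seed must be an integer")
  structure(list(
    n_genes = as.integer(n_genes),
    extension_log_mean = extension_log_mean,
    extension_log_sd = extension_log_sd,
    snp_per_kb = snp_per_kb,
    maf_min = maf_min, maf_max = maf_max,
    n_subjects = as.integer(n_subjects),
    causal = causal,
    age_mean = age_mean, age_sd = age_sd,
    age_log_or = age_log_or,
    age_maf_slope = age_maf_slope,
    subtype_spec = subtype_spec,
    baseline_log_odds = baseline_log_odds,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes (log-normal extension: meanlog %.3f, sdlog %.3f)\n",
              x$n_genes, x$extension_log_mean, x$extension_log_sd))
  cat(sprintf("  %.2f SNPs/kb, MAF U[%.2f, %.2f], %d subjects\n",
              x$snp_per_kb, x$maf_min, x$maf_max, x$n_subjects))
  cat(sprintf("  %d causal gene(s), seed %d\n",
              if (is.null(x$causal)) 0L else length(x$causal), x$seed))
  invisible(x)
}

# per-operation seed streams derived from the master seed (kept < 2^31)
.stream_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}
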