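#' Simulate gene annotations with skewed locus sizes
#'
#' Draws locus extensions from the configured log-normal distribution and
#' lays genes end to end on synthetic chromosomes, separated by 50 kb gaps so
#' that neither gene bodies nor their +/-10 kb windows overlap.  Coordinates
#' are 1-based inclusive; extension is `end - start + 1`.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 20, seed = 3))
#' summarize_annotation(ann)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stream_seed(config, 101L))
  n <- config$n_genes
  ext <- pmax(round(rlnorm(n, config$extension_log_mean,
                           config$extension_log_sd)), 200)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_chrom <- min(23L, n)
  chrom_idx <- rep_len(seq_len(n_chrom), n)
  gap <- 50000
  start <- numeric(n)
  offset <- numeric(n_chrom)
  for (i in seq_len(n)) {
    ci <- chrom_idx[i]
    start[i] <- offset[ci] + gap + 1
    offset[ci] <- start[i] + ext[i] - 1
  }
  data.frame(
    gene_id = .gene_id(seq_len(n)),
    chrom = paste0("chr", chrom_idx),
    start = start,
    end = start + ext - 1,
    strand = strand,
    stringsAsFactors = FALSE
  )
}

# truncated-normal ages on [20, 91] by rejection
.draw_ages <- function(n, mean, sd) {
  age <- rnorm(n, mean, sd)
  bad <- which(age < 20 | age > 91)
  while (length(bad)) {
    age[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[age[bad] < 20 | age[bad] > 91]
  }
  age
}

#' Simulate Hardy-Weinberg genotypes for an annotation
#'
#' The SNP count of each locus is Poisson with rate proportional to its
#' extension (`snp_per_kb` per kb, minimum one SNP); positions are uniform
#' within the gene body; each SNP has a minor allele frequency drawn uniform
#' on \[`maf_min`, `maf_max`\] and genotype dose drawn Binomial(2, MAF),
#' i.e. Hardy-Weinberg proportions.  With a non-zero `age_maf_slope` subject
#' ages are drawn here and the allele frequency varies on the logit scale
#' with age, making age a confounder of any genotype effect.
#'
#' @param annotation output of [simulate_annotation()].
#' @param config the same [sim_config()].
#' @return a `genotype_study` object: list with `map` (snp_id, chrom, pos,
#'   maf, origin_gene), integer dose matrix `dose` (subjects x SNPs),
#'   `subject_id`, and `age` (filled here only in confounded mode, otherwise
#'   by [simulate_phenotypes()]).
#' @export
simulate_genotypes <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(annotation) == 0) .stopf("annotation is empty")
  set.seed(.stream_seed(config, 211L))
  ext <- annotation$end - annotation$start + 1
  n_snp <- pmax(1L, rpois(nrow(annotation), config$snp_per_kb * ext / 1000))
  p <- sum(n_snp)
  n <- config$n_subjects

  gene_of <- rep(seq_len(nrow(annotation)), n_snp)
  pos <- unlist(lapply(seq_len(nrow(annotation)), function(i) {
    sort(sample.int(ext[i], n_snp[i])) + annotation$start[i] - 1
  }))
  maf <- runif(p, config$maf_min, config$maf_max)

  age <- NULL
  if (config$age_maf_slope != 0) {
    age <- .draw_ages(n, config$age_mean, config$age_sd)
    dage <- age - config$age_mean
    dose <- matrix(0L, n, p)
    for (j in seq_len(p)) {
      pj <- plogis(qlogis(maf[j]) + config$age_maf_slope * dage)
      dose[, j] <- rbinom(n, 2L, pj)
    }
  } else {
    dose <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
  }
  snp_id <- .snp_id(seq_len(p))
  colnames(dose) <- snp_id

  map <- data.frame(
    snp_id = snp_id,
    chrom = annotation$chrom[gene_of],
    pos = pos,
    maf = maf,
    origin_gene = annotation$gene_id[gene_of],
    stringsAsFactors = FALSE
  )
  structure(list(
    map = map,
    dose = dose,
    subject_id = sprintf("sub%05d", seq_len(n)),
    status = NULL, age = age, subtype = NULL, truth = NULL
  ), class = "genotype_study")
}

#' @export
print.genotype_study <- function(x, ...) {
  cat(sprintf("<genotype_study> %d subjects x %d SNPs (%d loci)\n",
              nrow(x$dose), ncol(x$dose),
              length(unique(x$map$origin_gene))))
  if (!is.null(x$status))
    cat(sprintf("  %d cases / %d controls\n", sum(x$status), sum(!x$status)))
  invisible(x)
}

#' Simulate case-control status, age and tumour subtype
#'
#' Disease status follows an additive logistic model:
#' `logit P(case) = baseline + sum_g beta_g * dose_g + age_log_or * (age -
#' age_mean)`.  One causal SNP per causal gene is selected deterministically
#' (the median-position SNP of the locus) and recorded in `$truth`.  When a
#' `subtype_spec` is configured, each subject carries a latent subtype drawn
#' from the spec's weights and that subtype's per-allele effects enter the
#' model; the label is kept for cases and set to `NA` for controls.
#'
#' @param study output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return the study with `status`, `age`, `subtype` and `truth` filled.
#' @export
simulate_phenotypes <- function(study, config) {
  stopifnot(inherits(study, "genotype_study"), inherits(config, "sim_config"))
  if (is.null(study$dose)) .stopf("genotypes missing")
  set.seed(.stream_seed(config, 307L))
  n <- nrow(study$dose)

  age <- study$age
  if (is.null(age)) age <- .draw_ages(n, config$age_mean, config$age_sd)
  lp <- rep(config$baseline_log_odds, n) +
    config$age_log_or * (age - config$age_mean)

  spec <- config$subtype_spec
  subtype_lat <- NULL
  causal_genes <- character(0)
  if (!is.null(spec)) {
    w <- spec$weights / sum(spec$weights)
    subtype_lat <- sample(names(w), n, replace = TRUE, prob = w)
    causal_genes <- unique(unlist(lapply(spec$log_or, names)))
  }
  if (!is.null(config$causal))
    causal_genes <- unique(c(causal_genes, names(config$causal)))

  truth <- NULL
  if (length(causal_genes)) {
    missing_g <- setdiff(causal_genes, study$map$origin_gene)
    if (length(missing_g))
      .stopf("causal gene(s) absent from annotation: %s",
             paste(missing_g, collapse = ", "))
    causal_snp <- vapply(causal_genes, function(g) {
      idx <- which(study$map$origin_gene == g)
      idx[ceiling(length(idx) / 2)]
    }, integer(1))
    names(causal_snp) <- causal_genes

    for (g in causal_genes) {
      d <- study$dose[, causal_snp[[g]]]
      if (!is.null(spec)) {
        beta <- vapply(subtype_lat, function(s) {
          b <- spec$log_or[[s]][g]
          if (is.null(b) || is.na(b)) 0 else b
        }, numeric(1))
      } else beta <- 0
      if (!is.null(config$causal) && g %in% names(config$causal) &&
          is.null(spec))
        beta <- config$causal[[g]]
      lp <- lp + beta * d
    }
    truth <- list(
      causal = data.frame(
        gene_id = causal_genes,
        snp_id = study$map$snp_id[causal_snp],
        log_or = if (is.null(spec)) unname(config$causal[causal_genes])
                 else NA_real_,
        stringsAsFactors = FALSE),
      subtype_spec = spec)
  }

  status <- rbinom(n, 1L, plogis(lp))
  subtype <- rep(NA_character_, n)
  if (!is.null(subtype_lat)) subtype[status == 1L] <- subtype_lat[status == 1L]

  study$status <- status
  study$age <- age
  study$subtype <- subtype
  study$truth <- truth
  study
}

#' Simulate a full synthetic cohort in one call
#'
#' Convenience wrapper chaining [simulate_annotation()],
#' [simulate_genotypes()] and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @return list with `annotation` and `study`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes = 10, n_subjects = 100))
#' cohort$study
#' @export
simulate_cohort <- function(config) {
  annotation <- simulate_annotation(config)
  study <- simulate_genotypes(annotation, config)
  study <- simulate_phenotypes(study, config)
  list(annotation = annotation, study = study)
}

#' Simulate gene sets with a known enriched set
#'
#' Builds one "enriched" set that contains a configurable fraction of the
#' truly causal genes (mimicking a curated driver-gene set) plus random
#' fillers, and a panel of size-matched random null sets.
#'
#' @param annotation gene annotation `data.frame`.
#' @param truth the `$truth` element of a simulated study (may be `NULL`
#'   when `causal_fraction = 0`).
#' @param set_size number of genes per set.
#' @param causal_fraction fraction of the enriched set drawn from the causal
#'   genes.
#' @param n_null_sets number of random sets of the same size.
#' @param seed RNG seed for this operation.
#' @return named list of character vectors (GMT-serialisable with
#'   [write_gmt()]); the enriched set is named `"enriched_set"`.
#' @export
simulate_gene_sets <- function(annotation, truth = NULL, set_size = 50,
                               causal_fraction = 0, n_null_sets = 10,
                               seed = 1L) {
  genes <- annotation$gene_id
  if (set_size > length(genes)) .stopf("set_size exceeds number of genes")
  set.seed(as.integer(seed))
  causal <- if (is.null(truth)) character(0) else truth$causal$gene_id
  n_causal <- round(causal_fraction * set_size)
  if (n_causal > length(causal))
    .stopf("requested %d causal genes but only %d exist", n_causal,
           length(causal))
  core <- if (n_causal > 0) causal[seq_len(n_causal)] else character(0)
  fill <- sample(setdiff(genes, core), set_size - length(core))
  sets <- list(enriched_set = c(core, fill))
  for (k in seq_len(n_null_sets))
    sets[[sprintf("null_set_%02d", k)]] <- sample(genes, set_size)
  sets
}

#' Simulate a 2x3 case-control genotype count table
#'
#' Controls are multinomial with the given genotype frequencies; case
#' genotype probabilities are the control frequencies with the odds of the
#' heterozygote and rare-homozygote classes multiplied by `or_het` and
#' `or_hom`, so the expected crude odds ratios equal those inputs.
#'
#' @param genotype_freqs_controls length-3 probabilities (hom-ref, het,
#'   hom-alt), summing to 1.
#' @param or_het,or_hom odds multipliers for the het and hom-alt classes.
#' @param n_controls,n_cases group sizes (both must be positive).
#' @param seed RNG seed.
#' @param snp_id label for the resulting table.
#' @return a [count_table()].
#' @examples
#' simulate_count_table(c(0.64, 0.32, 0.04), 1.5, 2.25, 500, 500, seed = 1)
#' @export
simulate_count_table <- function(genotype_freqs_controls, or_het, or_hom,
                                 n_controls, n_cases, seed = 1L,
                                 snp_id = "sim_snp") {
  f <- genotype_freqs_controls
  if (length(f) != 3 || any(f < 0) || abs(sum(f) - 1) > 1e-8)
    .stopf("genotype_freqs_controls must be 3 non-negative values summing to 1")
  if (n_cases < 1) .stopf("n_cases must be positive")
  if (n_controls < 1) .stopf("n_controls must be positive")
  if (or_het < 0 || or_hom < 0) .stopf("odds ratios must be non-negative")
  pc <- f * c(1, or_het, or_hom)
  pc <- pc / sum(pc)
  if (any(f * n_controls == 0) || any(pc * n_cases == 0))
    .warnf("a genotype class has zero expected count")
  set.seed(as.integer(seed))
  controls <- drop(rmultinom(1, n_controls, f))
  cases <- drop(rmultinom(1, n_cases, pc))
  count_table(snp_id, controls = controls, cases = cases)
}
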