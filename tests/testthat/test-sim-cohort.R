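test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(maf_min = 0), "maf_min")
  expect_error(sim_config(maf_min = 0.3, maf_max = 0.2), "maf_min")
  expect_error(sim_config(causal = c(0.5)), "causal")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("simulate_annotation: degenerate sd, moment recovery, determinism", {
  cfg0 <- sim_config(n_genes = 20, extension_log_sd = 0, seed = 4)
  ann0 <- simulate_annotation(cfg0)
  expect_true(all(ann0$end - ann0$start + 1 ==
                  round(exp(cfg0$extension_log_mean))))

  cfg <- sim_config(n_genes = 5000, seed = 1)
  ann <- simulate_annotation(cfg)
  ext <- ann$end - ann$start + 1
  # closed-form log-normal moments as oracle
  mu_true <- exp(cfg$extension_log_mean + cfg$extension_log_sd^2 / 2)
  sd_true <- mu_true * sqrt(exp(cfg$extension_log_sd^2) - 1)
  expect_lt(abs(mean(ext) - mu_true), 3 * sd_true / sqrt(5000))

  expect_identical(ann, simulate_annotation(cfg))

  # genes never overlap on a chromosome
  by_chrom <- split(ann, ann$chrom)
  for (b in by_chrom) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
})

test_that("simulate_genotypes: HWE proportions, Poisson SNP counts, determinism", {
  cfg <- sim_config(n_genes = 2, n_subjects = 10000, maf_min = 0.5,
                    maf_max = 0.5, seed = 2)
  ann <- simulate_annotation(cfg)
  study <- simulate_genotypes(ann, cfg)
  props <- table(factor(study$dose[, 1], levels = 0:2)) / nrow(study$dose)
  expect_lt(max(abs(props - c(0.25, 0.5, 0.25))), 4 * sqrt(0.25 / 10000))

  # Poisson mean oracle: 1 SNP/kb on 50 kb genes -> mean count ~ 50
  cfg2 <- sim_config(n_genes = 1000, extension_log_mean = log(50000),
                     extension_log_sd = 0, snp_per_kb = 1, n_subjects = 2,
                     seed = 3)
  ann2 <- simulate_annotation(cfg2)
  st2 <- simulate_genotypes(ann2, cfg2)
  counts <- table(st2$map$origin_gene)
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 1000))

  expect_identical(study$dose, simulate_genotypes(ann, cfg)$dose)
})

test_that("HWE test p-values are uniform across simulated null SNPs", {
  # the exact test is conservative and discrete by construction, so the
  # uniformity check targets the chi-square variant
  cfg <- sim_config(n_genes = 5000, extension_log_sd = 0,
                    extension_log_mean = log(2000), snp_per_kb = 0.5,
                    n_subjects = 500, seed = 9)
  ann <- simulate_annotation(cfg)
  study <- simulate_genotypes(ann, cfg)
  idx <- seq_len(min(5000, ncol(study$dose)))
  ps <- vapply(idx, function(j) {
    cnt <- table(factor(study$dose[, j], levels = 0:2))
    hwe_test(as.numeric(cnt), method = "chisq")$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate_phenotypes: null model prevalence and truth recording", {
  cfg <- sim_config(n_genes = 3, n_subjects = 8000,
                    baseline_log_odds = qlogis(0.3), seed = 6)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$study$status) - 0.3), 4 * sqrt(0.3 * 0.7 / 8000))
  expect_null(co$study$truth)
  expect_true(all(co$study$age >= 20 & co$study$age <= 91))

  cfg2 <- sim_config(n_genes = 3, n_subjects = 500,
                     causal = c(g0002 = log(2)), seed = 6)
  co2 <- simulate_cohort(cfg2)
  expect_equal(co2$study$truth$causal$gene_id, "g0002")
  expect_true(co2$study$truth$causal$snp_id %in%
              co2$study$map$snp_id[co2$study$map$origin_gene == "g0002"])

  cfg3 <- sim_config(n_genes = 3, causal = c(nope = 1), seed = 6)
  ann <- simulate_annotation(cfg3)
  st <- simulate_genotypes(ann, cfg3)
  expect_error(simulate_phenotypes(st, cfg3), "absent")
})

test_that("subtype-specific effects produce differing subtype ORs", {
  spec <- list(weights = c(neg = 0.4, pos = 0.6),
               log_or = list(neg = c(g0001 = log(2.2)), pos = c(g0001 = 0)))
  cfg <- sim_config(n_genes = 1, extension_log_mean = log(2000),
                    extension_log_sd = 0, snp_per_kb = 0.1,
                    n_subjects = 12000, subtype_spec = spec, seed = 11)
  co <- simulate_cohort(cfg)
  st <- co$study
  snp <- st$truth$causal$snp_id[1]
  d <- st$dose[, snp]
  cnt <- function(mask) as.numeric(table(factor(d[mask], levels = 0:2)))
  ctrl <- cnt(st$status == 0)
  tneg <- count_table(snp, ctrl, cnt(st$status == 1 &
                                     st$subtype == "neg" & !is.na(st$subtype)))
  tpos <- count_table(snp, ctrl, cnt(st$status == 1 &
                                     st$subtype == "pos" & !is.na(st$subtype)))
  int <- subtype_interaction(tneg, tpos)
  expect_gt(int$or_subtype_neg$or_point, int$or_subtype_pos$or_point)
  expect_lt(int$p_interaction, 0.05)
})

test_that("simulate_gene_sets builds enriched and null sets deterministically", {
  cfg <- sim_config(n_genes = 100, n_subjects = 50,
                    causal = c(g0010 = 1, g0020 = 1), seed = 3)
  co <- simulate_cohort(cfg)
  sets <- simulate_gene_sets(co$annotation, co$study$truth, set_size = 10,
                             causal_fraction = 0.2, n_null_sets = 4, seed = 7)
  expect_length(sets, 5)
  expect_true(all(c("g0010", "g0020") %in% sets$enriched_set))
  expect_true(all(lengths(sets) == 10))
  expect_identical(sets, simulate_gene_sets(co$annotation, co$study$truth,
                                            set_size = 10,
                                            causal_fraction = 0.2,
                                            n_null_sets = 4, seed = 7))
  expect_error(simulate_gene_sets(co$annotation, co$study$truth,
                                  set_size = 10, causal_fraction = 1,
                                  seed = 1), "causal")
})

test_that("simulate_count_table: expected ORs, errors, determinism", {
  tab <- simulate_count_table(c(0.64, 0.32, 0.04), or_het = 1, or_hom = 1,
                              n_controls = 50000, n_cases = 50000, seed = 8)
  ors <- genotype_or(tab)
  expect_true(all(ors$or_point > 0.95 & ors$or_point < 1.05))
  expect_error(simulate_count_table(c(0.6, 0.3, 0.1), 1, 1, 100, 0),
               "n_cases")
  expect_error(simulate_count_table(c(0.6, 0.3, 0.2), 1, 1, 10, 10), "sum")
  t1 <- simulate_count_table(c(0.5, 0.4, 0.1), 1.5, 2, 200, 200, seed = 3)
  t2 <- simulate_count_table(c(0.5, 0.4, 0.1), 1.5, 2, 200, 200, seed = 3)
  expect_identical(t1, t2)
})
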