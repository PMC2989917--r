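test_that("hwe_test: exact HWE proportions give chi-square 0, p = 1", {
  got <- hwe_test(c(25, 50, 25), method = "chisq")
  expect_equal(got$chisq, 0)
  expect_equal(got$p, 1)
})

test_that("hwe_test matches the expected-count formula oracle on printed counts", {
  counts <- c(693, 165, 10)
  got <- hwe_test(counts, method = "chisq")
  q <- (2 * 10 + 165) / (2 * 868)
  e <- 868 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((counts - e)^2 / e)
  expect_equal(got$chisq, stat, tolerance = 1e-12)
  expect_equal(got$p, pchisq(stat, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("exact hwe_test equals a direct enumeration oracle", {
  # oracle: conditional pmf of the heterozygote count given the rare-allele
  # count, written from the counting formula with choose()
  oracle_exact <- function(cnt) {
    n <- sum(cnt); nr <- 2 * cnt[3] + cnt[2]
    hs <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
    lp <- vapply(hs, function(h) {
      na <- (nr - h) / 2
      lchoose(n, na) + lchoose(n - na, h) + h * log(2) -
        lchoose(2 * n, nr)
    }, numeric(1))
    pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[hs == cnt[2]] + 1e-12])
  }
  for (cnt in list(c(60, 30, 10), c(83, 13, 4), c(40, 45, 15),
                   c(200, 180, 60), c(10, 5, 5))) {
    expect_equal(hwe_test(cnt, method = "exact")$p, oracle_exact(cnt),
                 tolerance = 1e-10)
  }
})

test_that("hwe_test: exact and chi-square variants track each other", {
  # the exact test is discrete, so pointwise agreement is bounded by the
  # pmf step size; assert the realistic envelope at n = 500
  set.seed(12)
  diffs <- c()
  for (i in 1:100) {
    maf <- runif(1, 0.2, 0.5)
    n <- 500
    cnt <- as.numeric(table(factor(rbinom(n, 2, maf), levels = 0:2)))
    q <- (2 * cnt[3] + cnt[2]) / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    if (min(e) < 10) next
    diffs <- c(diffs, abs(hwe_test(cnt, method = "chisq")$p -
                          hwe_test(cnt, method = "exact")$p))
  }
  expect_gt(length(diffs), 50)
  expect_lt(mean(diffs), 0.05)
  expect_lt(max(diffs), 0.2)
})

test_that("hwe_test flags monomorphic input with p = 1", {
  got <- hwe_test(c(100, 0, 0))
  expect_equal(got$p, 1)
  expect_equal(got$flag, "monomorphic")
})

test_that("genotype_or reproduces the printed early-onset table exactly", {
  ors <- genotype_or(table2_cdkl2())
  expect_equal(round(ors$or_point[1], 2), 1.21)
  expect_equal(round(ors$ci_low[1], 2), 0.66)
  expect_equal(round(ors$ci_high[1], 2), 2.23)
  expect_equal(round(ors$or_point[2], 2), 0.35)
  expect_equal(round(ors$ci_low[2], 2), 0.11)
  expect_equal(round(ors$ci_high[2], 2), 1.12)
})

test_that("genotype_or: identical case/control rows give OR 1; zero cells flagged", {
  tab <- count_table("x", c(50, 30, 10), c(50, 30, 10))
  ors <- genotype_or(tab)
  expect_equal(ors$or_point, c(1, 1))
  tab0 <- count_table("x", c(50, 30, 0), c(50, 30, 5))
  ors0 <- genotype_or(tab0)
  expect_equal(ors0$flag[2], "zero_cell")
  expect_true(is.na(ors0$or_point[2]))
})

test_that("model_or: null table gives OR 1, p 1 for every model", {
  tab <- count_table("x", c(50, 30, 10), c(50, 30, 10))
  for (m in c("trend", "dominant", "recessive")) {
    got <- model_or(tab, m)
    expect_equal(got$or_point, 1, tolerance = 1e-8)
    expect_equal(got$p_value, 1, tolerance = 1e-6)
  }
})

test_that("trend OR equals an independent aggregated logistic fit", {
  set.seed(31)
  for (i in 1:10) {
    ctrl <- rmultinom(1, 300, c(0.5, 0.4, 0.1))[, 1]
    case <- rmultinom(1, 350, c(0.45, 0.4, 0.15))[, 1]
    tab <- count_table("x", ctrl, case)
    got <- model_or(tab, "trend")
    d <- data.frame(dose = rep(c(0, 1, 2), 2), status = rep(c(0, 1), each = 3),
                    w = c(ctrl, case))
    fit <- glm(status ~ dose, family = binomial(), data = d, weights = w)
    expect_equal(got$or_point, exp(unname(coef(fit)["dose"])),
                 tolerance = 1e-6)
  }
})

test_that("swapping cases and controls reciprocates ORs and swaps CI bounds", {
  tab <- table2_cdkl2()
  swp <- count_table("x", controls = tab$cases, cases = tab$controls)
  for (m in c("dominant", "recessive")) {
    a <- model_or(tab, m); b <- model_or(swp, m)
    expect_equal(b$or_point, 1 / a$or_point, tolerance = 1e-8)
    expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-8)
    expect_equal(b$ci_high, 1 / a$ci_low, tolerance = 1e-8)
  }
})

test_that("Wald, LRT and score p-values agree asymptotically", {
  set.seed(44)
  cfg <- sim_config(n_genes = 1, extension_log_mean = log(5000),
                    extension_log_sd = 0, snp_per_kb = 0.1,
                    n_subjects = 20000, causal = c(g0001 = log(1.2)),
                    seed = 91)
  co <- simulate_cohort(cfg)
  snp <- co$study$truth$causal$snp_id
  d <- co$study$dose[, snp]
  cnt <- function(mask) as.numeric(table(factor(d[mask], levels = 0:2)))
  tab <- count_table(snp, cnt(co$study$status == 0), cnt(co$study$status == 1))
  ps <- vapply(c("lrt", "wald", "score"), function(m)
    model_or(tab, "trend", p_method = m)$p_value, numeric(1))
  expect_lt(max(ps) - min(ps), 0.005)
})

test_that("stratified_or: single stratum equals crude; MH matches textbook formula", {
  set.seed(19)
  n <- 600
  subj <- data.frame(status = rbinom(n, 1, 0.5), dose = rbinom(n, 2, 0.3),
                     age = runif(n, 47, 55))  # all in one stratum
  crude_tab <- count_table(
    "x",
    as.numeric(table(factor(subj$dose[subj$status == 0], levels = 0:2))),
    as.numeric(table(factor(subj$dose[subj$status == 1], levels = 0:2))))
  expect_warning(adj <- stratified_or(subj, model = "trend"), "stratum")
  crude <- model_or(crude_tab, "trend")
  expect_equal(adj$or_point, crude$or_point, tolerance = 1e-7)

  # hand-sized two-stratum MH oracle
  t1 <- count_table("x", c(30, 15, 5), c(20, 20, 10))
  t2 <- count_table("x", c(50, 10, 2), c(45, 12, 3))
  got <- stratified_or(list(a = t1, b = t2), model = "dominant", method = "mh")
  mh_or <- function(tabs) {
    num <- den <- 0
    for (tb in tabs) {
      a <- sum(tb$cases[2:3]); b <- tb$cases[1]
      cc <- sum(tb$controls[2:3]); d <- tb$controls[1]
      n_i <- a + b + cc + d
      num <- num + a * d / n_i
      den <- den + b * cc / n_i
    }
    num / den
  }
  expect_equal(got$or_point, unname(mh_or(list(t1, t2))), tolerance = 1e-12)
})

test_that("permutation_trend_p: exhaustive oracle on a toy, determinism", {
  subj <- data.frame(status = c(1, 1, 1, 0, 0, 0, 0, 1),
                     dose = c(2, 1, 1, 0, 0, 1, 0, 2))
  got <- permutation_trend_p(subj, exhaustive = TRUE)
  combos <- combn(8, 4)
  z_obs <- trend_test(subj$dose, subj$status)$z
  zs <- apply(combos, 2, function(ix) {
    s <- integer(8); s[ix] <- 1L
    trend_test(subj$dose, s)$z
  })
  expect_equal(got$p, mean(abs(zs) >= abs(z_obs) - 1e-12, na.rm = TRUE))

  p1 <- permutation_trend_p(subj, B = 500, seed = 5)
  p2 <- permutation_trend_p(subj, B = 500, seed = 5)
  expect_equal(p1$p, p2$p)
  expect_lt(abs(p1$p - got$p), 0.1)
})

test_that("subtype_interaction: identical tables give p = 1; printed counts run", {
  tabs <- table3_bmpr1a()
  same <- subtype_interaction(tabs$neg, tabs$neg)
  expect_equal(same$p_interaction, 1, tolerance = 1e-8)

  int <- subtype_interaction(tabs$neg, tabs$pos)
  # crude trend ORs approximate the printed (age-adjusted) 0.79 / 1.02
  expect_equal(int$or_subtype_neg$or_point, 0.776, tolerance = 0.01)
  expect_equal(int$or_subtype_pos$or_point, 1.001, tolerance = 0.01)
  expect_true(int$p_interaction > 0 && int$p_interaction <= 1)
  # oracle: explicit Wald z on the difference of the two log ORs
  b <- function(case) {
    d <- data.frame(dose = rep(c(0, 1, 2), 2), status = rep(c(0, 1), each = 3),
                    w = c(514, 306, 50, case))
    f <- glm(status ~ dose, family = binomial(), data = d, weights = w)
    c(coef(f)["dose"], vcov(f)["dose", "dose"])
  }
  bn <- b(c(189, 96, 8)); bp <- b(c(389, 243, 34))
  z <- (bn[1] - bp[1]) / sqrt(bn[2] + bp[2])
  expect_equal(int$p_interaction, unname(2 * pnorm(-abs(z))), tolerance = 1e-10)

  int2 <- subtype_interaction(tabs$neg, tabs$pos, method = "case_only_trend")
  expect_true(int2$p_interaction > 0 && int2$p_interaction <= 1)

  small <- count_table("x", c(514, 306, 50), c(5, 3, 1))
  expect_equal(subtype_interaction(small, tabs$pos)$flag, "small_sample")
})

test_that("count tables round-trip through TSV and JSON readers", {
  d <- data.frame(snp = rep("rs1", 2), group = c("controls", "cases"),
                  n_AA = c(39, 62), n_Aa = c(28, 54), n_aa = c(9, 5))
  f_tsv <- tempfile(fileext = ".tsv")
  data.table::fwrite(d, f_tsv, sep = "\t")
  got <- read_count_tables(f_tsv)[["rs1"]]
  expect_equal(unname(got$controls), c(39, 28, 9))
  expect_equal(unname(got$cases), c(62, 54, 5))
  f_json <- tempfile(fileext = ".json")
  jsonlite::write_json(d, f_json)
  got2 <- read_count_tables(f_json)[["rs1"]]
  expect_equal(got2$controls, got$controls)
})

test_that("genotype study round-trips through the TSV directory format", {
  cfg <- sim_config(n_genes = 4, n_subjects = 40, seed = 15)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  write_study(co$study, dir)
  back <- read_study(dir)
  expect_equal(unname(back$dose), unname(co$study$dose))
  expect_equal(back$status, co$study$status)
  expect_equal(back$age, co$study$age, tolerance = 1e-6)
})
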