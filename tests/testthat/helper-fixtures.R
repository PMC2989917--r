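# Shared fixtures: printed replication-study tables and toy study builders.

# rs6852678 / CDKL2, early-onset stratum (controls C/C,C/T,T/T then cases)
table2_cdkl2 <- function() {
  count_table("rs6852678", controls = c(39, 28, 9), cases = c(62, 54, 5))
}

# rs3732568 / EPHB1 whole-study counts
table1_ephb1 <- function() {
  count_table("rs3732568", controls = c(693, 165, 10), cases = c(891, 172, 8))
}

# rs12765929 / BMPR1A by ER-alpha tumour status (shared controls)
table3_bmpr1a <- function() {
  list(neg = count_table("rs12765929", controls = c(514, 306, 50),
                         cases = c(189, 96, 8)),
       pos = count_table("rs12765929", controls = c(514, 306, 50),
                         cases = c(389, 243, 34)))
}

# deterministic toy study: n subjects, explicit doses/ages, 2 one-SNP genes
toy_study <- function(dose, status, age,
                      gene_of = rep("gA", ncol(dose))) {
  colnames(dose) <- sprintf("s%02d", seq_len(ncol(dose)))
  map <- data.frame(snp_id = colnames(dose), chrom = "chr1",
                    pos = seq_len(ncol(dose)) * 1000,
                    origin_gene = gene_of, stringsAsFactors = FALSE)
  structure(list(map = map, dose = dose,
                 subject_id = sprintf("sub%02d", seq_len(nrow(dose))),
                 status = status, age = age, subtype = NULL, truth = NULL),
            class = "genotype_study")
}

toy_locus_map <- function(study) {
  a <- data.frame(snp_id = study$map$snp_id, gene_id = study$map$origin_gene,
                  stringsAsFactors = FALSE)
  tab <- table(a$gene_id)
  structure(list(assignments = a,
                 n_snps = stats::setNames(as.integer(tab), names(tab)),
                 window_bp = 10000), class = "locus_map")
}

# independent oracle: partial-correlation t built from explicit residual fits
oracle_partial_t <- function(dose, status, age) {
  rs <- stats::residuals(stats::lm(status ~ age))
  rd <- stats::residuals(stats::lm(dose ~ age))
  r <- stats::cor(rs, rd)
  n <- length(dose)
  t <- r * sqrt((n - 3) / (1 - r^2))
  list(t = t, p = 2 * stats::pt(abs(t), n - 3, lower.tail = FALSE))
}

# independent oracle: Cochran-Armitage chi-square from weighted proportions
oracle_trend_chisq <- function(tab2x3) {
  # tab2x3: rows controls/cases, columns dose 0/1/2
  w <- c(0, 1, 2)
  n <- colSums(tab2x3); r <- tab2x3[2, ]
  N <- sum(n); R <- sum(r)
  num <- sum(w * r) - R * sum(w * n) / N
  den <- R / N * (1 - R / N) * (sum(n * w^2) - sum(n * w)^2 / N)
  num^2 / den
}
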