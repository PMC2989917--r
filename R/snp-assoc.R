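#' Two-degree-of-freedom genotypic association test
#'
#' Pearson chi-square on the case-control by genotype contingency table
#' (2 x 3, or 2 x 2 when a genotype class is absent, then 1 df).  No
#' continuity correction.  Missing doses are excluded pairwise.
#'
#' @param dose_vector genotype doses in `{0, 1, 2, NA}`.
#' @param status 0/1 case-control status, same length.
#' @return list with `statistic`, `df`, `p` (`NA` with `flag =
#'   "constant_dose"` when fewer than two genotype classes remain).
#' @examples
#' genotypic_test(c(0, 0, 1, 1, 2, 2), c(0, 1, 0, 1, 0, 1))$p  # identical rows
#' @export
genotypic_test <- function(dose_vector, status) {
  ok <- !is.na(dose_vector) & !is.na(status)
  d <- dose_vector[ok]; s <- status[ok]
  if (length(unique(d)) < 2 || length(unique(s)) < 2)
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                flag = "constant_dose"))
  tab <- table(factor(s, levels = c(0, 1)), d)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       flag = NULL)
}

# residuals of y on [1, x] by least squares (x may be constant -> mean-centre)
.resid_on <- function(y, x) {
  if (var(x) == 0) return(y - mean(y))
  b <- cov(y, x) / var(x)
  y - mean(y) - b * (x - mean(x))
}

#' Age-adjusted partial-correlation t test under the additive model
#'
#' Residualises both status and genotype dose on age (least squares with
#' intercept), correlates the residuals, and converts the partial
#' correlation to a t statistic: `t = r * sqrt((n - 3) / (1 - r^2))` with
#' `n - 3` degrees of freedom.  When age is constant the plain Pearson
#' correlation is used with `n - 2` df and the result is flagged.
#'
#' @param dose_vector genotype doses in `{0, 1, 2, NA}`.
#' @param status 0/1 status.
#' @param age age in years.
#' @return list with `t`, `p`, `df`, `n_used`, `r`, and `flag` (`NULL`,
#'   `"age_constant"`, or `"perfect_correlation"` when |r| = 1, in which case
#'   `t` is `Inf` with matching sign and `p = 0`).
#' @export
additive_partial_t <- function(dose_vector, status, age) {
  ok <- complete.cases(dose_vector, status, age)
  d <- as.numeric(dose_vector[ok]); s <- as.numeric(status[ok])
  a <- as.numeric(age[ok])
  n <- length(d)
  if (n < 5) .stopf("need at least 5 complete observations, got %d", n)
  if (var(d) == 0)
    return(list(t = NA_real_, p = NA_real_, df = NA_integer_, n_used = n,
                r = NA_real_, flag = "constant_dose"))
  flag <- NULL
  if (var(a) == 0) {
    rs <- s - mean(s); rd <- d - mean(d)
    df <- n - 2L
    flag <- "age_constant"
  } else {
    rs <- .resid_on(s, a); rd <- .resid_on(d, a)
    df <- n - 3L
  }
  if (var(rs) == 0)
    return(list(t = NA_real_, p = NA_real_, df = df, n_used = n,
                r = NA_real_, flag = "constant_status"))
  r <- sum(rs * rd) / sqrt(sum(rs^2) * sum(rd^2))
  if (abs(r) >= 1 - 1e-12) {
    return(list(t = sign(r) * Inf, p = 0, df = df, n_used = n, r = sign(r),
                flag = "perfect_correlation"))
  }
  t <- r * sqrt(df / (1 - r^2))
  list(t = t, p = 2 * pt(abs(t), df, lower.tail = FALSE), df = df,
       n_used = n, r = r, flag = flag)
}

#' Cochran-Armitage trend test
#'
#' Score test for a linear trend in case proportion across genotype doses
#' with weights 0/1/2, without continuity correction.  The signed statistic
#' `z` is positive when the case proportion increases with dose.
#'
#' @inheritParams genotypic_test
#' @return list with `z`, `p` (two-sided), `flag`.
#' @export
trend_test <- function(dose_vector, status) {
  ok <- !is.na(dose_vector) & !is.na(status)
  d <- dose_vector[ok]; s <- status[ok]
  if (length(unique(d)) < 2 || length(unique(s)) < 2)
    return(list(z = NA_real_, p = NA_real_, flag = "constant_dose"))
  w <- c(0, 1, 2)
  n_g <- vapply(w, function(v) sum(d == v), numeric(1))
  r_g <- vapply(w, function(v) sum(d == v & s == 1), numeric(1))
  N <- sum(n_g); R <- sum(r_g)
  num <- sum(w * (r_g - n_g * R / N))
  v <- R / N * (1 - R / N) * (sum(n_g * w^2) - sum(n_g * w)^2 / N)
  if (v <= 0) return(list(z = NA_real_, p = NA_real_, flag = "zero_variance"))
  z <- num / sqrt(v)
  list(z = z, p = 2 * pnorm(abs(z), lower.tail = FALSE), flag = NULL)
}

# Vectorised partial-correlation t over the columns of a complete dose
# matrix.  Returns t, r, df for each column; columns with zero variance get
# NA.  Shared by snp_association() and the permutation engine.
.partial_t_matrix <- function(dose, status, age) {
  n <- nrow(dose)
  X <- cbind(1, age)
  qx <- qr(X)
  D <- qr.resid(qx, dose)
  u <- qr.resid(qx, as.numeric(status))
  dn <- sqrt(colSums(D^2))
  un <- sqrt(sum(u^2))
  r <- as.numeric(crossprod(D, u)) / (dn * un)
  bad <- dn < 1e-10
  r[bad] <- NA_real_
  df <- n - 3L
  t <- r * sqrt(df / pmax(1 - r^2, 1e-300))
  t[!is.na(r) & abs(r) >= 1 - 1e-12] <-
    sign(r[!is.na(r) & abs(r) >= 1 - 1e-12]) * Inf
  list(t = t, r = r, df = df)
}

#' Per-SNP association scan over a genotype study
#'
#' Runs any combination of the genotypic (2 df), age-adjusted partial-t
#' (additive), and Cochran-Armitage trend tests over every SNP of a study.
#' SNPs with complete data go through a vectorised matrix path for the
#' partial-t; SNPs with missing doses fall back to pairwise deletion.
#'
#' @param study a `genotype_study` with phenotypes filled.
#' @param tests subset of `c("partial_t", "genotypic", "trend")`.
#' @return `data.frame` with one row per SNP: `snp_id`, `n_used`, and the
#'   requested columns `t_additive`, `p_additive`, `p_genotypic`, `p_trend`.
#' @export
snp_association <- function(study,
                            tests = c("partial_t", "genotypic", "trend")) {
  stopifnot(inherits(study, "genotype_study"))
  if (is.null(study$status) || is.null(study$age))
    .stopf("study needs status and age; run simulate_phenotypes() or load them")
  tests <- match.arg(tests, c("partial_t", "genotypic", "trend"),
                     several.ok = TRUE)
  dose <- study$dose
  p <- ncol(dose)
  out <- data.frame(snp_id = colnames(dose),
                    n_used = colSums(!is.na(dose)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL

  if ("partial_t" %in% tests) {
    t_add <- rep(NA_real_, p); p_add <- rep(NA_real_, p)
    complete <- !anyNA(study$status) && !anyNA(study$age)
    miss_col <- colSums(is.na(dose)) > 0
    if (complete && any(!miss_col)) {
      idx <- which(!miss_col)
      res <- .partial_t_matrix(dose[, idx, drop = FALSE],
                               study$status, study$age)
      t_add[idx] <- res$t
      p_add[idx] <- 2 * pt(abs(res$t), res$df, lower.tail = FALSE)
      p_add[idx][is.infinite(res$t)] <- 0
    }
    slow <- if (complete) which(miss_col) else seq_len(p)
    for (j in slow) {
      r <- additive_partial_t(dose[, j], study$status, study$age)
      t_add[j] <- r$t; p_add[j] <- r$p
    }
    out$t_additive <- t_add
    out$p_additive <- p_add
  }
  if ("genotypic" %in% tests)
    out$p_genotypic <- vapply(seq_len(p), function(j)
      genotypic_test(dose[, j], study$status)$p, numeric(1))
  if ("trend" %in% tests)
    out$p_trend <- vapply(seq_len(p), function(j)
      trend_test(dose[, j], study$status)$p, numeric(1))
  out
}
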