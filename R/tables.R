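#' Case-control genotype count table
#'
#' The atom of the replication statistics: counts of the three genotype
#' classes (hom-ref, het, hom-alt, with "ref" the major allele) in controls
#' and cases.
#'
#' @param snp_id SNP label.
#' @param controls,cases length-3 non-negative integer counts
#'   `(n_AA, n_Aa, n_aa)`.
#' @return object of class `genotype_count_table`.
#' @examples
#' count_table("rs6852678", controls = c(39, 28, 9), cases = c(62, 54, 5))
#' @export
count_table <- function(snp_id, controls, cases) {
  if (length(controls) != 3 || length(cases) != 3)
    .stopf("controls and cases must each have 3 genotype counts")
  if (any(controls < 0) || any(cases < 0)) .stopf("counts must be >= 0")
  if (sum(controls) == 0 || sum(cases) == 0)
    .stopf("each group needs a positive total")
  structure(list(snp_id = snp_id,
                 controls = setNames(as.numeric(controls),
                                     c("n_AA", "n_Aa", "n_aa")),
                 cases = setNames(as.numeric(cases),
                                  c("n_AA", "n_Aa", "n_aa"))),
            class = "genotype_count_table")
}

#' @export
print.genotype_count_table <- function(x, ...) {
  cat(sprintf("<genotype_count_table> %s\n", x$snp_id))
  m <- rbind(controls = x$controls, cases = x$cases)
  print(m)
  invisible(x)
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Chi-square (1 df, no continuity correction) against the HWE expectation
#' derived from the estimated allele frequency, or the exact conditional
#' test (enumeration of heterozygote counts given the minor-allele count).
#' `method = "auto"` uses the exact test for totals up to 500.
#' Monomorphic samples return p = 1 with a flag.
#'
#' @param counts length-3 genotype counts `(n_AA, n_Aa, n_aa)`, typically
#'   controls.
#' @param method `"auto"`, `"chisq"` or `"exact"`.
#' @return list with `p`, `method`, `chisq` (when applicable), `flag`.
#' @examples
#' hwe_test(c(693, 165, 10), method = "chisq")
#' @export
hwe_test <- function(counts, method = c("auto", "chisq", "exact")) {
  method <- match.arg(method)
  if (length(counts) != 3 || any(counts < 0)) .stopf("need 3 counts >= 0")
  n <- sum(counts)
  if (n == 0) .stopf("empty table")
  n_aa <- counts[3]; n_het <- counts[2]; n_AA <- counts[1]
  n_minor <- 2 * n_aa + n_het
  if (n_minor == 0 || n_minor == 2 * n) {
    return(list(p = 1, method = "monomorphic", chisq = 0,
                flag = "monomorphic"))
  }
  if (method == "auto") method <- if (n <= 500) "exact" else "chisq"
  if (method == "chisq") {
    q <- n_minor / (2 * n)
    e <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((counts - e)^2 / e)
    return(list(p = pchisq(stat, 1, lower.tail = FALSE), method = "chisq",
                chisq = stat, flag = NULL))
  }
  # exact: enumerate heterozygote counts with the observed allele count
  nr <- round(n_minor)                     # rare-allele copies
  het_vals <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  logprob <- vapply(het_vals, function(h) {
    na <- (nr - h) / 2                     # rare homozygotes
    nA <- n - na - h
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nA + 1) +
      h * log(2) + lgamma(nr + 1) + lgamma(2 * n - nr + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logprob - max(logprob))
  prob <- prob / sum(prob)
  p_obs <- prob[het_vals == round(n_het)]
  p <- sum(prob[prob <= p_obs + 1e-12])
  list(p = min(1, p), method = "exact", chisq = NA_real_, flag = NULL)
}

.or_wald <- function(a, b, c_, d, conf_level = 0.95) {
  # OR of exposure: (a/b) / (c_/d); a,b = case exposed/ref, c_,d = control
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (min(a, b, c_, d) == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                se = NA_real_, p = NA_real_, flag = "zero_cell"))
  lor <- log(a * d / (b * c_))
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = exp(lor), ci_low = exp(lor - z * se), ci_high = exp(lor + z * se),
       se = se, p = 2 * pnorm(abs(lor / se), lower.tail = FALSE), flag = NULL)
}

#' Per-genotype odds ratios with Wald intervals
#'
#' Cross-product odds ratios of the heterozygote and rare-homozygote classes
#' versus the common-homozygote reference, with Wald 95% confidence
#' intervals `exp(ln OR +/- z * sqrt(sum 1/cell))` and no continuity
#' correction.
#'
#' @param table a [count_table()].
#' @param conf_level confidence level (default 0.95).
#' @return `data.frame` with rows `genotype_het` and `genotype_hom`:
#'   `model`, `or_point`, `ci_low`, `ci_high`, `p_value`, `p_method`,
#'   `flag`.
#' @examples
#' tab <- count_table("rs6852678", c(39, 28, 9), c(62, 54, 5))
#' genotype_or(tab)  # het OR 1.21 (0.66-2.23), hom OR 0.35 (0.11-1.12)
#' @export
genotype_or <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "genotype_count_table"))
  if (table$controls[1] == 0 || table$cases[1] == 0)
    .stopf("reference genotype cell is empty")
  het <- .or_wald(table$cases[2], table$cases[1],
                  table$controls[2], table$controls[1], conf_level)
  hom <- .or_wald(table$cases[3], table$cases[1],
                  table$controls[3], table$controls[1], conf_level)
  out <- data.frame(
    model = c("genotype_het", "genotype_hom"),
    or_point = c(het$or, hom$or),
    ci_low = c(het$ci_low, hom$ci_low),
    ci_high = c(het$ci_high, hom$ci_high),
    p_value = c(het$p, hom$p),
    p_method = "wald",
    flag = c(if (is.null(het$flag)) NA_character_ else het$flag,
             if (is.null(hom$flag)) NA_character_ else hom$flag),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# aggregated subject rows of a count table: dose, status, weight
.table_rows <- function(table) {
  data.frame(dose = rep(c(0, 1, 2), 2),
             status = rep(c(0, 1), each = 3),
             w = c(table$controls, table$cases))
}

#' Trend, dominant and recessive odds ratios from a count table
#'
#' The trend OR comes from a single-parameter logistic regression of status
#' on genotype dose fitted to the aggregated table with frequency weights;
#' its CI is the Wald interval from the fit.  The dominant and recessive ORs
#' are cross-products of the collapsed 2x2 table with Wald CIs from cell
#' counts.  The p-value method matters at small counts: the default is the
#' likelihood-ratio test; `"wald"` and `"score"` (Cochran-Armitage for the
#' trend, Pearson for collapsed 2x2s) are also available.
#'
#' @param table a [count_table()].
#' @param model `"trend"`, `"dominant"` or `"recessive"`.
#' @param p_method `"lrt"` (default), `"wald"` or `"score"`.
#' @param conf_level confidence level.
#' @return one-row `data.frame`: `model`, `or_point`, `ci_low`, `ci_high`,
#'   `p_value`, `p_method`, `flag`.
#' @examples
#' tab <- count_table("rs6852678", c(39, 28, 9), c(62, 54, 5))
#' model_or(tab, "recessive")  # OR 0.32 (0.10-1.00), LRT p = 0.044
#' @export
model_or <- function(table, model = c("trend", "dominant", "recessive"),
                     p_method = c("lrt", "wald", "score"),
                     conf_level = 0.95) {
  stopifnot(inherits(table, "genotype_count_table"))
  model <- match.arg(model)
  p_method <- match.arg(p_method)
  z <- qnorm(1 - (1 - conf_level) / 2)
  d <- .table_rows(table)
  flag <- NA_character_

  if (model == "trend") {
    x <- d$dose
  } else if (model == "dominant") {
    x <- as.numeric(d$dose >= 1)
  } else {
    x <- as.numeric(d$dose == 2)
  }
  dd <- data.frame(status = d$status, x = x, w = d$w)
  if (model != "trend") {
    a <- sum(dd$w[dd$status == 1 & dd$x == 1])
    b <- sum(dd$w[dd$status == 1 & dd$x == 0])
    cc <- sum(dd$w[dd$status == 0 & dd$x == 1])
    e <- sum(dd$w[dd$status == 0 & dd$x == 0])
    wald <- .or_wald(a, b, cc, e, conf_level)
    or <- wald$or; ci_low <- wald$ci_low; ci_high <- wald$ci_high
    if (!is.null(wald$flag)) flag <- wald$flag
  }
  fit <- suppressWarnings(glm(status ~ x, family = binomial(),
                              data = dd, weights = w))
  fit0 <- suppressWarnings(glm(status ~ 1, family = binomial(),
                               data = dd, weights = w))
  if (model == "trend") {
    beta <- coef(fit)["x"]
    se <- sqrt(vcov(fit)["x", "x"])
    or <- exp(unname(beta))
    ci_low <- exp(unname(beta) - z * se)
    ci_high <- exp(unname(beta) + z * se)
  }
  p <- switch(p_method,
    lrt = {
      dev <- fit0$deviance - fit$deviance
      pchisq(dev, 1, lower.tail = FALSE)
    },
    wald = {
      beta <- coef(fit)["x"]; se <- sqrt(vcov(fit)["x", "x"])
      2 * pnorm(abs(beta / se), lower.tail = FALSE)
    },
    score = {
      if (model == "trend") {
        dose_vec <- rep(d$dose, d$w)
        status_vec <- rep(d$status, d$w)
        trend_test(dose_vec, status_vec)$p
      } else {
        m <- matrix(c(e, cc, b, a), 2, 2)
        expd <- outer(rowSums(m), colSums(m)) / sum(m)
        pchisq(sum((m - expd)^2 / expd), 1, lower.tail = FALSE)
      }
    })
  data.frame(model = model, or_point = or, ci_low = ci_low,
             ci_high = ci_high, p_value = unname(p), p_method = p_method,
             flag = flag, stringsAsFactors = FALSE)
}

.age_strata <- function(age, age_breaks) {
  cut(age, breaks = age_breaks, include.lowest = TRUE)
}

.model_x <- function(dose, model) {
  switch(model, trend = dose, dominant = as.numeric(dose >= 1),
         recessive = as.numeric(dose == 2))
}

#' Age-stratified (adjusted) odds ratio
#'
#' Adjusts the association for age either by unconditional logistic
#' regression with age-stratum indicator covariates (default; the strata are
#' the similar-size bands 20-46, 46-56, 56-66, 66-91) or by the
#' Mantel-Haenszel common odds ratio over per-stratum collapsed 2x2 tables
#' (with the Robins-Breslow-Greenland variance for the CI).
#'
#' @param subject_data `data.frame` with columns `status`, `dose`, `age`;
#'   or, for `method = "mh"`, a named list of [count_table()]s by stratum.
#' @param model `"trend"`, `"dominant"` or `"recessive"` (MH requires a
#'   collapsed model or trend treated per-copy is not supported: use
#'   dominant/recessive; logistic supports all three).
#' @param age_breaks stratum boundaries.
#' @param method `"logistic"` (default) or `"mh"`.
#' @param conf_level confidence level.
#' @return one-row `data.frame` like [model_or()], `p_method = "lrt"` for
#'   logistic, `"wald"` for MH.
#' @export
stratified_or <- function(subject_data, model = c("trend", "dominant",
                                                  "recessive"),
                          age_breaks = c(20, 46, 56, 66, 91),
                          method = c("logistic", "mh"), conf_level = 0.95) {
  model <- match.arg(model)
  method <- match.arg(method)
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (inherits(subject_data, "data.frame")) {
    sd_ <- subject_data
    stopifnot(all(c("status", "dose", "age") %in% names(sd_)))
    sd_ <- sd_[complete.cases(sd_[, c("status", "dose", "age")]), ]
    sd_$stratum <- .age_strata(sd_$age, age_breaks)
    tabs <- lapply(split(sd_, sd_$stratum, drop = TRUE), function(s) {
      x <- .model_x(s$dose, if (model == "trend") "dominant" else model)
      list(a = sum(s$status == 1 & x == 1), b = sum(s$status == 1 & x == 0),
           c = sum(s$status == 0 & x == 1), d = sum(s$status == 0 & x == 0))
    })
  } else if (is.list(subject_data)) {
    if (method != "mh")
      .stopf("count-table input supports method = 'mh' only")
    tabs <- lapply(subject_data, function(tb) {
      stopifnot(inherits(tb, "genotype_count_table"))
      xcase <- .model_x(c(0, 1, 2), model)
      list(a = sum(tb$cases[xcase == 1]), b = sum(tb$cases[xcase == 0]),
           c = sum(tb$controls[xcase == 1]), d = sum(tb$controls[xcase == 0]))
    })
  } else .stopf("subject_data must be a data.frame or a list of count tables")

  if (method == "mh") {
    if (model == "trend" && inherits(subject_data, "data.frame"))
      .stopf("Mantel-Haenszel requires a collapsed model (dominant/recessive)")
    informative <- vapply(tabs, function(t)
      (t$a + t$b) > 0 && (t$c + t$d) > 0 &&
        (t$a + t$c) > 0 && (t$b + t$d) > 0, logical(1))
    if (!all(informative))
      .warnf("%d stratum(s) carry zero weight", sum(!informative))
    tabs <- tabs[informative]
    if (length(tabs) == 0) .stopf("no informative stratum")
    n_i <- vapply(tabs, function(t) t$a + t$b + t$c + t$d, numeric(1))
    R_i <- vapply(tabs, function(t) t$a * t$d, numeric(1)) / n_i
    S_i <- vapply(tabs, function(t) t$b * t$c, numeric(1)) / n_i
    or <- sum(R_i) / sum(S_i)
    # Robins-Breslow-Greenland variance of log MH OR
    P_i <- vapply(tabs, function(t) (t$a + t$d), numeric(1)) / n_i
    Q_i <- vapply(tabs, function(t) (t$b + t$c), numeric(1)) / n_i
    v <- sum(P_i * R_i) / (2 * sum(R_i)^2) +
      sum(P_i * S_i + Q_i * R_i) / (2 * sum(R_i) * sum(S_i)) +
      sum(Q_i * S_i) / (2 * sum(S_i)^2)
    se <- sqrt(v)
    return(data.frame(model = model, or_point = or,
                      ci_low = exp(log(or) - z * se),
                      ci_high = exp(log(or) + z * se),
                      p_value = 2 * pnorm(abs(log(or) / se),
                                          lower.tail = FALSE),
                      p_method = "wald", flag = NA_character_,
                      stringsAsFactors = FALSE))
  }

  # unconditional logistic with stratum indicators
  sd_$x <- .model_x(sd_$dose, model)
  keep <- vapply(split(sd_$status, sd_$stratum),
                 function(s) length(unique(s)) == 2, logical(1))
  dropped <- names(keep)[!keep]
  if (length(dropped)) {
    .warnf("dropping stratum(s) without both cases and controls: %s",
           paste(dropped, collapse = ", "))
    sd_ <- sd_[!(as.character(sd_$stratum) %in% dropped), ]
  }
  if (nrow(sd_) == 0) .stopf("no informative stratum")
  sd_$stratum <- droplevels(sd_$stratum)
  has_strata <- nlevels(sd_$stratum) > 1
  f1 <- if (has_strata) status ~ x + stratum else status ~ x
  f0 <- if (has_strata) status ~ stratum else status ~ 1
  fit <- glm(f1, family = binomial(), data = sd_)
  fit0 <- glm(f0, family = binomial(), data = sd_)
  beta <- coef(fit)["x"]; se <- sqrt(vcov(fit)["x", "x"])
  data.frame(model = model, or_point = exp(unname(beta)),
             ci_low = exp(unname(beta) - z * se),
             ci_high = exp(unname(beta) + z * se),
             p_value = pchisq(fit0$deviance - fit$deviance, 1,
                              lower.tail = FALSE),
             p_method = "lrt", flag = NA_character_,
             stringsAsFactors = FALSE)
}

# signed trend score statistic, optionally summed over age strata
.trend_z <- function(status, dose, strata = NULL) {
  if (is.null(strata)) return(trend_test(dose, status)$z)
  num <- 0; v <- 0
  for (ii in split(seq_along(status), strata)) {
    if (length(unique(status[ii])) < 2 || length(unique(dose[ii])) < 2) next
    d <- dose[ii]; s <- status[ii]
    w <- c(0, 1, 2)
    n_g <- vapply(w, function(x) sum(d == x), numeric(1))
    r_g <- vapply(w, function(x) sum(d == x & s == 1), numeric(1))
    N <- sum(n_g); R <- sum(r_g)
    num <- num + sum(w * (r_g - n_g * R / N))
    v <- v + R / N * (1 - R / N) * (sum(n_g * w^2) - sum(n_g * w)^2 / N)
  }
  if (v <= 0) return(NA_real_)
  num / sqrt(v)
}

#' Permutation p-value for the trend statistic
#'
#' Permutes the case-control labels `B` times, recomputes the (optionally
#' age-stratum-adjusted) Cochran-Armitage trend statistic, and reports the
#' two-sided add-one p-value.  With `exhaustive = TRUE` all distinct
#' labelings are enumerated and the exact probability is returned.
#'
#' @param subject_data `data.frame` with `status`, `dose` and (if
#'   `adjusted`) `age`.
#' @param B number of permutations (warning below 100).
#' @param seed RNG seed.
#' @param adjusted compute the stratified score statistic within age bands.
#' @param age_breaks stratum boundaries.
#' @param exhaustive enumerate all labelings (toy data only).
#' @return list with `p`, `z_obs`, `B`, `adjusted`.
#' @export
permutation_trend_p <- function(subject_data, B = 10000, seed = 1L,
                                adjusted = FALSE,
                                age_breaks = c(20, 46, 56, 66, 91),
                                exhaustive = FALSE) {
  stopifnot(all(c("status", "dose") %in% names(subject_data)))
  if (!exhaustive && B < 100) .warnf("B < 100: permutation p will be coarse")
  status <- subject_data$status
  dose <- subject_data$dose
  strata <- NULL
  if (adjusted) {
    stopifnot("age" %in% names(subject_data))
    strata <- .age_strata(subject_data$age, age_breaks)
  }
  z_obs <- .trend_z(status, dose, strata)
  if (is.na(z_obs)) .stopf("trend statistic undefined on these data")
  if (exhaustive) {
    n <- length(status); n_case <- sum(status == 1)
    n_lab <- choose(n, n_case)
    if (n_lab > 2e5) .stopf("exhaustive enumeration infeasible")
    combos <- combn(n, n_case)
    zs <- apply(combos, 2, function(ix) {
      s <- integer(n); s[ix] <- 1L
      .trend_z(s, dose, strata)
    })
    p <- mean(abs(zs) >= abs(z_obs) - 1e-12, na.rm = TRUE)
    return(list(p = p, z_obs = z_obs, B = n_lab, adjusted = adjusted))
  }
  set.seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(B)) {
    zb <- .trend_z(sample(status), dose, strata)
    if (!is.na(zb) && abs(zb) >= abs(z_obs) - 1e-12) exceed <- exceed + 1L
  }
  list(p = (exceed + 1) / (B + 1), z_obs = z_obs, B = B, adjusted = adjusted)
}

#' Tumour-subtype interaction with a shared control group
#'
#' Estimates subtype-specific trend odds ratios (each subtype's cases versus
#' the common controls) and tests whether they differ.  The default test is
#' a Wald z on the difference of the two log odds ratios with summed
#' variances; the alternative is a case-only trend test (logistic regression
#' of subtype on dose among cases), which is more powerful when genotype and
#' subtype are independent in the source population.
#'
#' @param table_neg,table_pos [count_table()]s for the two subtypes; both
#'   must carry the same control counts.
#' @param method `"logor_diff_wald"` or `"case_only_trend"`.
#' @param conf_level confidence level for the subtype-specific CIs.
#' @return list of class `interaction_result`: `or_subtype_neg`,
#'   `or_subtype_pos` (each a one-row data.frame from [model_or()]),
#'   `p_interaction`, `method`, `flag` (`"small_sample"` when a subtype has
#'   fewer than 10 cases).
#' @export
subtype_interaction <- function(table_neg, table_pos,
                                method = c("logor_diff_wald",
                                           "case_only_trend"),
                                conf_level = 0.95) {
  stopifnot(inherits(table_neg, "genotype_count_table"),
            inherits(table_pos, "genotype_count_table"))
  method <- match.arg(method)
  if (!isTRUE(all.equal(table_neg$controls, table_pos$controls)))
    .stopf("the two subtype tables must share the same control counts")
  flag <- NULL
  if (sum(table_neg$cases) < 10 || sum(table_pos$cases) < 10)
    flag <- "small_sample"

  fit_trend <- function(tb) {
    d <- .table_rows(tb)
    fit <- suppressWarnings(glm(status ~ dose, family = binomial(),
                                data = d, weights = w))
    list(est = model_or(tb, "trend", p_method = "lrt",
                        conf_level = conf_level),
         beta = unname(coef(fit)["dose"]),
         var = vcov(fit)["dose", "dose"])
  }
  neg <- fit_trend(table_neg)
  pos <- fit_trend(table_pos)

  if (method == "logor_diff_wald") {
    zstat <- (neg$beta - pos$beta) / sqrt(neg$var + pos$var)
    p_int <- 2 * pnorm(abs(zstat), lower.tail = FALSE)
  } else {
    cases <- data.frame(
      dose = rep(c(0, 1, 2), 2),
      is_neg = rep(c(1, 0), each = 3),
      w = c(table_neg$cases, table_pos$cases))
    fit <- suppressWarnings(glm(is_neg ~ dose, family = binomial(),
                                data = cases, weights = w))
    fit0 <- suppressWarnings(glm(is_neg ~ 1, family = binomial(),
                                 data = cases, weights = w))
    p_int <- pchisq(fit0$deviance - fit$deviance, 1, lower.tail = FALSE)
  }
  structure(list(or_subtype_neg = neg$est, or_subtype_pos = pos$est,
                 p_interaction = unname(p_int), method = method, flag = flag),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat(sprintf("<interaction_result> method = %s\n", x$method))
  cat(sprintf("  subtype-negative trend OR %.2f (%.2f-%.2f)\n",
              x$or_subtype_neg$or_point, x$or_subtype_neg$ci_low,
              x$or_subtype_neg$ci_high))
  cat(sprintf("  subtype-positive trend OR %.2f (%.2f-%.2f)\n",
              x$or_subtype_pos$or_point, x$or_subtype_pos$ci_low,
              x$or_subtype_pos$ci_high))
  cat(sprintf("  p_interaction = %.4g%s\n", x$p_interaction,
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
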