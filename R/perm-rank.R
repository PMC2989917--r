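#' Observed per-gene maximum |t| statistic
#'
#' For every gene in the locus map, takes the maximum absolute value of the
#' age-adjusted partial-correlation t statistic over the gene's assigned
#' SNPs.  SNPs with undefined t (constant dose) are skipped; genes left with
#' no defined statistic are omitted.
#'
#' @param study a `genotype_study` with phenotypes.
#' @param locus_map a `locus_map`.
#' @return `data.frame` with `gene_id`, `M_obs`, `n_snps`, `best_snp_id`
#'   (attribute `snp_stats` holds the per-SNP t values used).
#' @export
observed_max_stat <- function(study, locus_map) {
  stopifnot(inherits(study, "genotype_study"), inherits(locus_map, "locus_map"))
  assoc <- snp_association(study, tests = "partial_t")
  a <- merge(locus_map$assignments, assoc, by = "snp_id")
  a <- a[!is.na(a$t_additive), , drop = FALSE]
  if (nrow(a) == 0) .stopf("no gene has a defined t statistic")
  a$abs_t <- abs(a$t_additive)
  a <- a[order(a$gene_id, -a$abs_t, a$snp_id), ]
  first <- !duplicated(a$gene_id)
  res <- data.frame(
    gene_id = a$gene_id[first],
    M_obs = a$abs_t[first],
    n_snps = as.integer(table(a$gene_id)[a$gene_id[first]]),
    best_snp_id = a$snp_id[first],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "snp_stats") <- a[, c("snp_id", "gene_id", "t_additive")]
  res
}

# matrix of permuted status vectors (n x B); optionally within age strata
.permute_status <- function(status, age, B, stratify_age, age_breaks) {
  n <- length(status)
  if (!stratify_age)
    return(vapply(seq_len(B), function(b) sample(status), numeric(n)))
  strata <- cut(age, breaks = age_breaks, include.lowest = TRUE)
  out <- matrix(0, n, B)
  idx_by <- split(seq_len(n), strata)
  for (b in seq_len(B)) {
    s <- status
    for (ii in idx_by) if (length(ii) > 1) s[ii] <- sample(status[ii])
    out[, b] <- s
  }
  out
}

#' Permutation-adjusted gene-level significance of the max-|t| statistic
#'
#' The locus-size correction: one set of `B` case-control label permutations
#' is drawn and shared across all genes and SNPs (preserving inter-SNP
#' correlation); for each permutation all per-SNP partial-correlation t
#' statistics are recomputed with the permuted status (age stays attached to
#' its subject) and each gene's null maximum |t| is compared with its
#' observed maximum.  The adjusted p-value uses the add-one estimator
#' `(exceedances + 1) / (B + 1)`, so it lies in `[1/(B+1), 1]`.  Because the
#' null maximum of a SNP-rich gene is itself larger, the adjusted rank no
#' longer favours long loci.
#'
#' With `exhaustive = TRUE` all distinct case-control labelings are
#' enumerated (only feasible for toy data; capped at 200,000 labelings) and
#' the exact probability `#\{null max >= M_obs\} / #labelings` is returned.
#'
#' @param study a `genotype_study` with phenotypes.
#' @param locus_map a `locus_map`.
#' @param B number of permutations.
#' @param seed RNG seed.
#' @param stratify_age permute within age strata instead of freely.
#' @param age_breaks stratum boundaries used when `stratify_age = TRUE`.
#' @param exhaustive enumerate all labelings instead of sampling.
#' @param block_size permutations processed per matrix block (memory knob).
#' @param max_cells workload guard: error if `B * n_snps` exceeds it.
#' @return list with `results` (`gene_id`, `M_obs`, `n_snps`,
#'   `exceed_count`, `B`, `p_adj`) and `ranked` (a `ranked_gene_list` ordered
#'   by `p_adj`, ties broken by larger `M_obs` then gene id).
#' @export
permutation_adjusted_p <- function(study, locus_map, B = 10000, seed = 1L,
                                   stratify_age = FALSE,
                                   age_breaks = c(20, 46, 56, 66, 91),
                                   exhaustive = FALSE, block_size = 250,
                                   max_cells = 2e9) {
  stopifnot(inherits(study, "genotype_study"), inherits(locus_map, "locus_map"))
  status <- study$status; age <- study$age
  if (is.null(status) || length(unique(status)) < 2)
    .stopf("status must contain both cases and controls")
  obs <- observed_max_stat(study, locus_map)
  snp_stats <- attr(obs, "snp_stats")
  snp_ids <- unique(snp_stats$snp_id)
  dose <- study$dose[, snp_ids, drop = FALSE]
  n <- nrow(dose)

  if (anyNA(dose)) {
    # pairwise deletion inside a shared-permutation engine is only exact per
    # SNP; mean-imputing the (few) missing doses keeps the shared null while
    # changing t negligibly -- flagged so callers can pre-filter instead.
    .warnf("dose matrix contains missing values; mean-imputed for permutations")
    mu <- colMeans(dose, na.rm = TRUE)
    for (j in which(colSums(is.na(dose)) > 0))
      dose[is.na(dose[, j]), j] <- mu[j]
  }

  if (exhaustive) {
    n_case <- sum(status == 1)
    n_lab <- choose(n, n_case)
    if (n_lab > 2e5) .stopf("exhaustive enumeration infeasible: %g labelings",
                            n_lab)
    combos <- combn(n, n_case)
    S <- matrix(0, n, ncol(combos))
    for (b in seq_len(ncol(combos))) S[combos[, b], b] <- 1
    B_eff <- ncol(combos)
  } else {
    if (as.double(B) * length(snp_ids) > max_cells)
      .stopf("workload B * n_snps = %g exceeds max_cells = %g; lower B or shard",
             as.double(B) * length(snp_ids), max_cells)
    set.seed(as.integer(seed))
    S <- .permute_status(status, age, B, stratify_age, age_breaks)
    B_eff <- B
  }

  X <- cbind(1, age)
  qx <- qr(X)
  D <- qr.resid(qx, dose)
  dn <- sqrt(colSums(D^2))
  keep <- dn > 1e-10
  D <- D[, keep, drop = FALSE]
  dn <- dn[keep]
  snp_ids <- snp_ids[keep]
  Dn <- sweep(D, 2, dn, "/")
  gene_of <- snp_stats$gene_id[match(snp_ids, snp_stats$snp_id)]
  gene_idx <- match(gene_of, obs$gene_id)
  df <- n - 3L
  thresh_t <- obs$M_obs[gene_idx]          # per-SNP threshold = its gene's M_obs
  # |t| >= M  <=>  |r| >= M / sqrt(df + M^2)  (monotone map, same df for all)
  thresh_r <- ifelse(is.infinite(thresh_t), 1, thresh_t / sqrt(df + thresh_t^2))
  thresh_r <- thresh_r - 1e-9   # ties (incl. the identity labeling) count as exceedances

  exceed <- integer(nrow(obs))
  for (b0 in seq(1, B_eff, by = block_size)) {
    b1 <- min(b0 + block_size - 1, B_eff)
    U <- qr.resid(qx, S[, b0:b1, drop = FALSE])
    un <- sqrt(colSums(U^2))
    un[un < 1e-300] <- Inf
    Un <- sweep(U, 2, un, "/")
    R <- abs(crossprod(Dn, Un))            # n_snps x block of |r|
    E <- R >= thresh_r                     # SNP-level exceedance
    ge <- rowsum(E + 0L, gene_idx)         # per-gene exceedance counts
    g_present <- as.integer(rownames(ge))
    exceed[g_present] <- exceed[g_present] + as.integer(rowSums(ge > 0))
  }

  res <- obs[, c("gene_id", "M_obs", "n_snps")]
  res$exceed_count <- exceed
  res$B <- B_eff
  res$p_adj <- if (exhaustive) exceed / B_eff else (exceed + 1) / (B_eff + 1)

  ord <- order(res$p_adj, -res$M_obs, res$gene_id)
  ranked <- data.frame(gene_id = res$gene_id[ord],
                       p_value = res$p_adj[ord],
                       statistic = res$M_obs[ord],
                       n_snps = res$n_snps[ord],
                       best_snp_id = obs$best_snp_id[ord],
                       stringsAsFactors = FALSE)
  rownames(ranked) <- NULL
  class(ranked) <- c("ranked_gene_list", "data.frame")
  list(results = res, ranked = ranked)
}
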