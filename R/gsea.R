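#' Convert a ranked gene list to ranked scores for enrichment
#'
#' @param ranked_list a `ranked_gene_list`.
#' @param score `"neglog10p"` (default, `-log10` of the gene p-value) or
#'   `"statistic"` (the gene statistic, e.g. the max |t|).
#' @return `data.frame` with `gene_id`, `score`, ordered by decreasing
#'   score (the order of the ranked list is preserved; both choices are
#'   monotone in it).
#' @export
as_ranked_scores <- function(ranked_list, score = c("neglog10p", "statistic")) {
  stopifnot(inherits(ranked_list, "ranked_gene_list"))
  score <- match.arg(score)
  s <- switch(score,
              neglog10p = -log10(pmax(ranked_list$p_value,
                                      .Machine$double.xmin)),
              statistic = abs(ranked_list$statistic))
  data.frame(gene_id = ranked_list$gene_id, score = s,
             stringsAsFactors = FALSE)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list from top to bottom, incrementing a running sum by
#' `|score|^weight_p / N_R` at each member of the set (`N_R` = sum of the
#' weighted member scores) and decrementing by `1 / (N - N_H)` at each
#' non-member.  The enrichment score is the running-sum value of maximal
#' absolute deviation from zero (signed).  With `weight_p = 0` this is the
#' classical unweighted KS deviation and the walk ends exactly at zero.
#'
#' @param ranked_scores `data.frame` with `gene_id`, `score`, in rank order.
#' @param membership character vector of member gene ids (at least one and
#'   not all of the list).
#' @param weight_p score-weighting exponent (GSEA default 1).
#' @return list with `es`, `running` (the full running-sum profile),
#'   `n_h`, and `flag` (`"zero_weight_fallback"` when all member scores are
#'   zero and the unweighted walk was used).
#' @export
enrichment_score <- function(ranked_scores, membership, weight_p = 1) {
  stopifnot(all(c("gene_id", "score") %in% names(ranked_scores)))
  N <- nrow(ranked_scores)
  hit <- ranked_scores$gene_id %in% membership
  n_h <- sum(hit)
  if (n_h < 1) .stopf("gene set has no member on the list")
  if (n_h >= N) .stopf("gene set covers the entire list")
  flag <- NULL
  w <- abs(ranked_scores$score)^weight_p
  n_r <- sum(w[hit])
  if (weight_p > 0 && n_r == 0) {
    flag <- "zero_weight_fallback"
    w <- rep(1, N)
    n_r <- n_h
  }
  inc <- ifelse(hit, w / n_r, -1 / (N - n_h))
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, n_h = n_h, flag = flag)
}

#' Gene-set significance by random-set permutation
#'
#' For each set, the null distribution of the enrichment score is built from
#' `n_perm` random gene-label sets of identical size drawn from the ranked
#' list.  The normalised enrichment score (NES) divides ES by the mean
#' absolute null ES of matching sign; the nominal p is the add-one
#' proportion of same-sign null ES at least as extreme; the FDR q uses the
#' GSEA ratio-of-tails over the pooled null NES of all sets.
#'
#' @param ranked_scores `data.frame` with `gene_id`, `score`.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm random sets per gene set (warning below 50: FDR unstable).
#' @param seed RNG seed.
#' @param weight_p score-weighting exponent.
#' @param min_size,max_size sets whose overlap with the list falls outside
#'   these bounds are skipped.
#' @return `data.frame` of class `gene_set_results`: `set_name`, `n_h`,
#'   `es`, `nes`, `p_nominal`, `q_fdr`.
#' @export
set_significance <- function(ranked_scores, gene_sets, n_perm = 1000,
                             seed = 1L, weight_p = 1, min_size = 5,
                             max_size = 5000) {
  if (n_perm < 50) .warnf("n_perm < 50: FDR estimates will be unstable")
  N <- nrow(ranked_scores)
  sizes <- vapply(gene_sets, function(s)
    sum(ranked_scores$gene_id %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep)) .stopf("no gene set within the size bounds intersects the list")
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  set.seed(as.integer(seed))

  es_obs <- vapply(gene_sets, function(s)
    enrichment_score(ranked_scores, s, weight_p)$es, numeric(1))

  # one null panel per distinct set size, shared by all sets of that size:
  # sets with identical membership are guaranteed identical results
  ids <- ranked_scores$gene_id
  null_by_size <- list()
  for (sz in sort(unique(sizes))) {
    null_by_size[[as.character(sz)]] <- vapply(seq_len(n_perm), function(b)
      enrichment_score(ranked_scores, sample(ids, sz), weight_p)$es,
      numeric(1))
  }
  null_es <- do.call(rbind, lapply(sizes, function(sz)
    null_by_size[[as.character(sz)]]))

  nes <- numeric(length(gene_sets))
  p_nom <- numeric(length(gene_sets))
  null_nes <- null_es
  for (i in seq_along(gene_sets)) {
    pos <- null_es[i, null_es[i, ] >= 0]
    neg <- null_es[i, null_es[i, ] < 0]
    m_pos <- if (length(pos)) mean(pos) else NA_real_
    m_neg <- if (length(neg)) mean(abs(neg)) else NA_real_
    null_nes[i, ] <- ifelse(null_es[i, ] >= 0,
                            null_es[i, ] / m_pos, null_es[i, ] / m_neg)
    if (es_obs[i] >= 0) {
      nes[i] <- es_obs[i] / m_pos
      p_nom[i] <- (sum(pos >= es_obs[i]) + 1) / (length(pos) + 1)
    } else {
      nes[i] <- es_obs[i] / m_neg
      p_nom[i] <- (sum(neg <= es_obs[i]) + 1) / (length(neg) + 1)
    }
  }

  pool <- as.numeric(null_nes)
  q <- vapply(seq_along(gene_sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num <- mean(pool[pool >= 0] >= nes[i])
      den <- mean(nes[nes >= 0] >= nes[i])
    } else {
      num <- mean(pool[pool < 0] <= nes[i])
      den <- mean(nes[nes < 0] <= nes[i])
    }
    if (is.nan(num) || is.nan(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  res <- data.frame(set_name = names(gene_sets), n_h = sizes, es = es_obs,
                    nes = nes, p_nominal = p_nom, q_fdr = q,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("gene_set_results", "data.frame")
  res
}

#' Benjamini-Hochberg correction within hypothesis groups
#'
#' Applies the BH step-up adjustment to the nominal p-values independently
#' within each hypothesis group (e.g. prognosis / treatment / somatic
#' alteration sets), reflecting that different biological hypotheses are
#' examined independently.
#'
#' @param results a `gene_set_results` data.frame.
#' @param grouping named character vector mapping `set_name` to group.  Sets
#'   without a group form their own singleton groups.
#' @return `results` with a `p_bh_group` column filled.
#' @export
group_fdr <- function(results, grouping) {
  stopifnot(inherits(results, "data.frame"),
            all(c("set_name", "p_nominal") %in% names(results)))
  g <- grouping[results$set_name]
  g[is.na(g)] <- paste0(".singleton.", which(is.na(g)))
  results$p_bh_group <- ave(results$p_nominal, g,
                            FUN = function(p) p.adjust(p, method = "BH"))
  results
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
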