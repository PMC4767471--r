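#' Rank genes by a two-group signal-to-noise metric
#'
#' Expression values are log2(count + 1) transformed (disable with
#' `transform = "none"`), then each gene gets the signal-to-noise ratio
#' (difference of group means over the sum of group standard deviations,
#' each SD floored at 0.2 |mean| and at 0.2 absolute to keep
#' near-constant genes finite). Genes are ordered by descending metric with
#' ties broken by gene label, so the ranking is deterministic.
#'
#' @param counts Genes x samples numeric matrix with gene rownames.
#' @param groups Factor/vector of sample group labels, length `ncol(counts)`.
#' @param group_a,group_b The two groups to contrast (metric is a minus b).
#' @param transform `"log2"` (default) or `"none"`.
#' @return Data frame `gene`, `metric` in ranked (descending) order.
#' @export
rank_genes <- function(counts, groups, group_a, group_b,
                       transform = c("log2", "none")) {
  transform <- match.arg(transform)
  groups <- as.character(groups)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs at least 2 samples")
  x <- if (transform == "log2") log2(counts + 1) else counts
  metric <- .snr_metric(x, ia, ib)
  ord <- order(-metric, rownames(counts))
  data.frame(gene = rownames(counts)[ord], metric = metric[ord],
             stringsAsFactors = FALSE)
}

.snr_metric <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(x[, ia, drop = FALSE])
  mb <- rowMeans(x[, ib, drop = FALSE])
  sa <- sqrt(pmax(rowSums(x[, ia, drop = FALSE]^2) - na * ma^2, 0) / (na - 1))
  sb <- sqrt(pmax(rowSums(x[, ib, drop = FALSE]^2) - nb * mb^2, 0) / (nb - 1))
  sa <- pmax(sa, 0.2 * abs(ma), 0.2)
  sb <- pmax(sb, 0.2 * abs(mb), 0.2)
  (ma - mb) / (sa + sb)
}

.es_core <- function(weight, hit) {
  # weight: |metric|^p in ranked order; hit: logical membership in that order
  n_hit <- sum(hit)
  nr <- sum(weight[hit])
  inc <- numeric(length(hit))
  inc[hit] <- if (nr > 0) weight[hit] / nr else 1 / n_hit
  inc[!hit] <- -1 / (length(hit) - n_hit)
  dev <- cumsum(inc)
  # first position attaining the maximal deviation, with a tolerance so that
  # exact +/- ties are not broken by floating-point noise in the cumsum
  m <- max(abs(dev))
  dev[which(abs(dev) >= m - 1e-9)[1]]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic gene-set running-sum statistic: walking down the ranked list,
#' hits increment the sum by `|metric|^weight_p` (normalized by the set
#' total) and misses decrement by 1/(N - set size); the score is the signed
#' maximal deviation from zero, in [-1, 1]. With `weight_p = 0` this is the
#' unweighted Kolmogorov-Smirnov statistic between hit and miss positions.
#'
#' @param ranked Ranked gene list from [rank_genes()] (or any data frame
#'   with `gene` and `metric` in ranked order).
#' @param gene_set Character vector of member genes; must be a nonempty
#'   proper subset of the ranked genes.
#' @param weight_p Metric weighting exponent (default 1).
#' @return The enrichment score.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  if (!length(gene_set)) stop("empty gene set")
  hit <- ranked$gene %in% gene_set
  if (!any(hit)) stop("gene set has no members in the ranked list")
  if (all(hit)) stop("gene set covers the whole list; no misses to score against")
  if (!all(gene_set %in% ranked$gene))
    stop("gene set contains genes absent from the ranked list")
  .es_core(abs(ranked$metric)^weight_p, hit)
}

#' Chromosome gene sets from a gene map
#'
#' @param genes Data frame with columns `gene` and `chrom`.
#' @param drop_sex Drop X/Y sets (default `FALSE`; the sex chromosomes are
#'   informative in hypodiploid ALL but confounded in mixed-sex cohorts).
#' @return Named list of gene-identifier vectors, one per chromosome.
#' @export
chromosome_gene_sets <- function(genes, drop_sex = FALSE) {
  sets <- split(genes$gene, genes$chrom)
  if (drop_sex) sets <- sets[setdiff(names(sets), c("X", "Y"))]
  sets
}

.label_permutations <- function(n, n_a, n_perm, seed) {
  # returns a list of index vectors (positions assigned to group a)
  total <- choose(n, n_a)
  if (n < 8 || total <= n_perm) {
    combs <- utils::combn(n, n_a)
    lapply(seq_len(ncol(combs)), function(j) combs[, j])
  } else {
    withr::with_seed(seed, {
      lapply(seq_len(n_perm), function(j) sample.int(n, n_a))
    })
  }
}

#' Permutation significance for chromosome gene sets
#'
#' Phenotype-label permutation test for the enrichment score: sample labels
#' are reassigned (exhaustively when there are fewer than 8 samples or fewer
#' distinct assignments than `n_perm`), the ranking and per-set scores are
#' recomputed for each relabeling, and each set gets a nominal p (fraction
#' of same-sign permuted scores at least as extreme), a normalized score NES
#' (observed over the mean same-sign permuted magnitude), and an FDR q from
#' the pooled permuted-NES null in the usual gene-set-enrichment fashion.
#'
#' @inheritParams rank_genes
#' @param gene_sets Named list of gene-identifier vectors (e.g.
#'   [chromosome_gene_sets()]).
#' @param n_perm Number of label permutations (>= 100 unless exhaustive).
#' @param weight_p Metric weighting exponent (default 1).
#' @param seed Integer seed (used only when permutations are sampled).
#' @return Data frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p`, `q`, `n_perm_used`, `exhaustive`.
#' @export
permutation_significance <- function(counts, groups, gene_sets, group_a, group_b,
                                     n_perm = 1000, weight_p = 1, seed = 1,
                                     transform = c("log2", "none")) {
  transform <- match.arg(transform)
  groups <- as.character(groups)
  keep <- groups %in% c(group_a, group_b)
  counts <- counts[, keep, drop = FALSE]
  groups <- groups[keep]
  n <- length(groups)
  n_a <- sum(groups == group_a)
  if (n_a < 2 || n - n_a < 2) stop("each group needs at least 2 samples")
  exhaustive <- n < 8 || choose(n, n_a) <= n_perm
  if (!exhaustive && n_perm < 100) stop("n_perm must be >= 100")
  x <- if (transform == "log2") log2(counts + 1) else counts
  gene_names <- rownames(counts)
  set_hits <- lapply(gene_sets, function(s) {
    if (!length(s)) stop("empty gene set")
    m <- gene_names %in% s
    if (!any(m) || all(m)) stop("gene set must be a nonempty proper subset")
    m
  })
  tie <- rank(gene_names, ties.method = "first")
  es_for_assignment <- function(ia) {
    metric <- .snr_metric(x, ia, setdiff(seq_len(n), ia))
    ord <- order(-metric, tie)
    w <- abs(metric[ord])^weight_p
    vapply(set_hits, function(h) .es_core(w, h[ord]), 0)
  }
  obs <- es_for_assignment(which(groups == group_a))
  perms <- .label_permutations(n, n_a, n_perm, seed)
  perm_es <- vapply(perms, es_for_assignment, obs)  # sets x perms
  if (length(gene_sets) == 1L) perm_es <- matrix(perm_es, nrow = 1)
  n_used <- length(perms)
  p <- nes <- numeric(length(obs))
  perm_nes <- matrix(NA_real_, nrow(perm_es), ncol(perm_es))
  for (i in seq_along(obs)) {
    same <- if (obs[i] >= 0) perm_es[i, ] >= 0 else perm_es[i, ] < 0
    if (!any(same)) { p[i] <- 0; nes[i] <- NA_real_; next }
    p[i] <- mean(abs(perm_es[i, same]) >= abs(obs[i]))
    norm <- mean(abs(perm_es[i, same]))
    nes[i] <- obs[i] / norm
    pos <- perm_es[i, ] >= 0
    pos_norm <- mean(perm_es[i, pos])
    neg_norm <- mean(abs(perm_es[i, !pos]))
    perm_nes[i, pos] <- perm_es[i, pos] / pos_norm
    perm_nes[i, !pos] <- perm_es[i, !pos] / neg_norm
  }
  q <- .gsea_fdr(nes, perm_nes)
  data.frame(set = names(gene_sets),
             size = vapply(set_hits, sum, 0L),
             es = obs, nes = nes, p = p, q = q,
             n_perm_used = n_used, exhaustive = exhaustive,
             stringsAsFactors = FALSE, row.names = NULL)
}

.gsea_fdr <- function(nes, perm_nes) {
  pool <- perm_nes[is.finite(perm_nes)]
  q <- rep(NA_real_, length(nes))
  for (i in seq_along(nes)) {
    if (!is.finite(nes[i])) next
    if (nes[i] >= 0) {
      denom_pool <- sum(pool >= 0)
      num <- if (denom_pool) sum(pool >= nes[i]) / denom_pool else 0
      denom_obs_n <- sum(nes >= 0, na.rm = TRUE)
      den <- sum(nes >= nes[i], na.rm = TRUE) / denom_obs_n
    } else {
      denom_pool <- sum(pool < 0)
      num <- if (denom_pool) sum(pool <= nes[i]) / denom_pool else 0
      denom_obs_n <- sum(nes < 0, na.rm = TRUE)
      den <- sum(nes <= nes[i], na.rm = TRUE) / denom_obs_n
    }
    q[i] <- min(1, if (den > 0) num / den else 0)
  }
  q
}

#' Copy-number versus methylation association test
#'
#' For each chromosome with at least `min_per_stratum` samples in both the
#' monosomic and the disomic stratum, computes the difference in mean beta
#' (disomic minus monosomic samples) averaged over the genes on that
#' chromosome, and a permutation p-value obtained by shuffling the
#' gene-to-chromosome assignment (which preserves the sample strata and the
#' gene-level beta distributions). P-values are Benjamini-Hochberg adjusted
#' across chromosomes.
#'
#' @param beta Genes x samples matrix of beta values in [0,1].
#' @param genes Data frame with `gene`, `chrom` matching `rownames(beta)`.
#' @param copy_number Chromosome x sample integer matrix of total copies
#'   (e.g. truth from [simulate_methylation()] or totals from
#'   [call_genome()] calls per sample).
#' @param mono_copy,di_copy Copy numbers defining the two strata (1 and 2).
#' @param min_per_stratum Minimum samples per stratum (default 2).
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame `chrom`, `n_genes`, `n_mono`, `n_di`, `delta_beta`,
#'   `p`, `q`.
#' @export
methylation_dosage_test <- function(beta, genes, copy_number,
                                    mono_copy = 1, di_copy = 2,
                                    min_per_stratum = 2, n_perm = 1000,
                                    seed = 1) {
  stopifnot(identical(rownames(beta), genes$gene),
            ncol(beta) == ncol(copy_number))
  chroms <- rownames(copy_number)
  testable <- Filter(function(ch) {
    sum(copy_number[ch, ] == mono_copy) >= min_per_stratum &&
      sum(copy_number[ch, ] == di_copy) >= min_per_stratum &&
      sum(genes$chrom == ch) >= 1
  }, chroms)
  if (!length(testable))
    stop("no chromosome with both copy-number strata; no contrast available")
  # per-gene stratum differences for each testable chromosome's sample split
  diff_mat <- vapply(testable, function(ch) {
    mono <- copy_number[ch, ] == mono_copy
    di <- copy_number[ch, ] == di_copy
    rowMeans(beta[, di, drop = FALSE]) - rowMeans(beta[, mono, drop = FALSE])
  }, numeric(nrow(beta)))
  labels <- genes$chrom
  obs <- vapply(seq_along(testable), function(j)
    mean(diff_mat[labels == testable[j], j]), 0)
  exceed <- integer(length(testable))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      lab_b <- sample(labels)
      d_b <- vapply(seq_along(testable), function(j)
        mean(diff_mat[lab_b == testable[j], j]), 0)
      exceed <- exceed + (abs(d_b) >= abs(obs))
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(chrom = testable,
             n_genes = vapply(testable, function(ch) sum(labels == ch), 0L),
             n_mono = vapply(testable, function(ch)
               sum(copy_number[ch, ] == mono_copy), 0L),
             n_di = vapply(testable, function(ch)
               sum(copy_number[ch, ] == di_copy), 0L),
             delta_beta = obs, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}
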