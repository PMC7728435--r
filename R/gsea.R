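# Preranked gene-set enrichment: sign(FC) x -log10(p) ranking metric,
# weighted Subramanian running-sum enrichment score, gene-set permutation
# null, NES and sign-stratified FDR.

#' Rank genes by signed significance
#'
#' Score = sign(effect) x (-log10 p), sorted descending. Zero p-values are
#' clamped to the smallest positive double with a log entry. Duplicate gene
#' ids keep the entry with the largest |score|; ties in score are broken by
#' gene id for reproducibility.
#'
#' @param results data frame with gene, effect and p-value columns (the
#'   output of [test_response_all()] / [test_differential_response()]).
#' @param gene_col,effect_col,p_col column names.
#' @return data frame of class `ranked_list` with columns `gene_id`,
#'   `score`, ordered by decreasing score.
#' @export
rank_genes <- function(results, gene_col = "gene_id", effect_col = "log2fc",
                       p_col = "pvalue") {
  if (nrow(results) == 0L) stopf("glucoMR_data_error", "empty results table")
  p <- results[[p_col]]
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stopf("glucoMR_data_error", "p-values must be finite and in [0, 1]")
  }
  if (any(p == 0)) {
    log_msg("info", "clamping %d zero p-value(s) to double.xmin", sum(p == 0))
    p[p == 0] <- .Machine$double.xmin
  }
  score <- sign(results[[effect_col]]) * (-log10(p))
  df <- data.frame(gene_id = as.character(results[[gene_col]]), score = score,
                   stringsAsFactors = FALSE)
  # duplicates: keep the largest |score|
  df <- df[order(-abs(df$score), df$gene_id), ]
  df <- df[!duplicated(df$gene_id), ]
  df <- df[order(-df$score, df$gene_id), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_list", "data.frame")
  df
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; members of `gene_set` increment the running sum by
#' |score|^weight (normalized over set members), non-members decrement it by
#' 1/(N - N_hit). ES is the signed maximum deviation from zero. Genes with
#' |score| = 0 contribute only to the miss side.
#'
#' @param ranked a `ranked_list`.
#' @param gene_set character vector of gene ids.
#' @param weight rank-weighting exponent (default 1, classic weighted).
#' @return list with `es` and `running` (the running-sum vector).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  hit <- ranked$gene_id %in% gene_set
  nh <- sum(hit)
  if (nh == 0L) stopf("glucoMR_data_error", "gene set does not intersect ranked list")
  N <- nrow(ranked)
  if (nh == N) return(list(es = 0, running = rep(0, N)))
  w <- abs(ranked$score)^weight
  w[abs(ranked$score) == 0] <- 0
  wh <- w * hit
  tot <- sum(wh)
  p_hit <- if (tot > 0) cumsum(wh) / tot else rep(0, N)
  p_miss <- cumsum(!hit) / (N - nh)
  running <- p_hit - p_miss
  list(es = running[which.max(abs(running))], running = running)
}

# O(k log k) ES from sorted hit positions (used in permutations); `w` is the
# precomputed |score|^weight vector over the ranked list.
es_from_positions <- function(pos, w, N) {
  pos <- sort(pos)
  k <- length(pos)
  if (k == N) return(0)
  wh <- w[pos]
  tot <- sum(wh)
  denom <- N - k
  j <- seq_len(k)
  if (tot == 0) {
    # all-zero hit weights: the running sum only decreases, reaching -1
    return(-1)
  }
  cum <- cumsum(wh) / tot
  after <- cum - (pos - j) / denom
  before <- c(0, cum[-k]) - (pos - j) / denom
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked GSEA with a gene-set permutation null
#'
#' For each gene set (after intersection with the ranked list and size
#' filtering), the null distribution of ES is built from `n_perm` random
#' same-size gene sets drawn from the ranked genes. NES divides ES by the
#' mean |null ES| of the same sign; the nominal p is the add-one-smoothed
#' same-sign permutation tail, and FDR follows the sign-stratified NES
#' procedure (fraction of pooled null NES at least as extreme, divided by
#' the fraction of observed NES at least as extreme, clipped to [0, 1]).
#'
#' @param ranked a `ranked_list`.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param n_perm permutations per set (>= 100).
#' @param min_size,max_size set-size bounds after intersection (15 and 500).
#' @param weight rank-weighting exponent.
#' @param seed RNG seed for the permutations.
#' @return data frame with set, size, es, nes, pvalue, fdr.
#' @export
gsea_preranked <- function(ranked, gene_sets, n_perm = 1000L, min_size = 15L,
                           max_size = 500L, weight = 1, seed = NULL) {
  if (n_perm < 100L) stopf("glucoMR_parameter_error", "n_perm must be >= 100")
  N <- nrow(ranked)
  sizes <- vapply(gene_sets, function(s) sum(ranked$gene_id %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    stopf("glucoMR_data_error", "no gene set within size bounds [%d, %d]",
          min_size, max_size)
  }
  gene_sets <- gene_sets[keep]
  sizes <- sizes[keep]
  # deterministic set order regardless of input order
  ord <- order(names(gene_sets))
  gene_sets <- gene_sets[ord]
  sizes <- sizes[ord]
  w <- abs(ranked$score)^weight
  w[abs(ranked$score) == 0] <- 0
  es_obs <- vapply(gene_sets, function(s)
    enrichment_score(ranked, s, weight)$es, numeric(1))
  with_seed(if (is.null(seed)) NULL else seed, {
    null_es <- lapply(sizes, function(k) {
      vapply(seq_len(n_perm), function(b)
        es_from_positions(sample.int(N, k), w, N), numeric(1))
    })
  })
  norm_one <- function(es, nulls) {
    same <- nulls[sign(nulls) == sign(es)]
    if (length(same) == 0L || es == 0) return(0)
    es / mean(abs(same))
  }
  nes_obs <- mapply(norm_one, es_obs, null_es)
  # each set's null ES normalized by its own same-sign mean, then pooled
  nes_null <- unlist(lapply(null_es, function(nulls) {
    out <- nulls
    pos <- nulls > 0
    neg <- nulls < 0
    if (any(pos)) out[pos] <- nulls[pos] / mean(nulls[pos])
    if (any(neg)) out[neg] <- nulls[neg] / mean(abs(nulls[neg]))
    out
  }))
  # nominal p: same-sign tail with add-one smoothing
  pvals <- mapply(function(es, nulls) {
    same <- nulls[sign(nulls) == sign(es) | nulls == 0]
    if (es == 0) return(1)
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }, es_obs, null_es)
  # sign-stratified FDR on NES
  fdr <- vapply(seq_along(nes_obs), function(i) {
    nes <- nes_obs[i]
    if (nes == 0) return(1)
    if (nes > 0) {
      null_frac <- mean(nes_null[nes_null >= 0] >= nes)
      obs_frac <- mean(nes_obs[nes_obs >= 0] >= nes)
    } else {
      null_frac <- mean(nes_null[nes_null <= 0] <= nes)
      obs_frac <- mean(nes_obs[nes_obs <= 0] <= nes)
    }
    if (is.nan(null_frac) || is.nan(obs_frac) || obs_frac == 0) return(1)
    min(1, null_frac / obs_frac)
  }, numeric(1))
  data.frame(set = names(gene_sets), size = sizes, es = es_obs, nes = nes_obs,
             pvalue = pvals, fdr = fdr, row.names = NULL,
             stringsAsFactors = FALSE)
}
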