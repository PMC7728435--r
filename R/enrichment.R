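# eSNP lookup for gene lists, eGene over-representation, GWAS p-value
# enrichment of an eSNP set (proportion below alpha, BH within the set,
# Bonferroni threshold, genomic-control lambda, QQ points), and the
# random-eGene permutation null.

#' Significant eSNPs for a gene list
#'
#' Unique SNP ids with eQTL FDR <= `fdr_max` for any listed gene in any
#' tissue.
#'
#' @param eqtl eQTL table (gene_id, snp_id, tissue, beta, se, pvalue, fdr).
#' @param genes character vector of gene ids.
#' @param fdr_max eQTL significance threshold (default 0.05).
#' @return character vector of SNP ids (possibly empty).
#' @export
esnps_for_genes <- function(eqtl, genes, fdr_max = 0.05) {
  if (length(genes) == 0L) stopf("glucoMR_data_error", "empty gene list")
  hit <- eqtl$gene_id %in% genes & eqtl$fdr <= fdr_max
  snps <- unique(eqtl$snp_id[hit])
  if (length(snps) == 0L) {
    log_msg("info", "no significant eSNPs for the %d listed gene(s)",
            length(genes))
  }
  snps
}

#' eGene over-representation in a gene list
#'
#' Two-proportion z-test comparing the eGene fraction among `genes` with
#' the fraction in the whole universe (two-sided).
#'
#' @param genes gene list (must be a subset of `universe_genes`).
#' @param universe_genes all analyzed genes.
#' @param egene_set genes with at least one significant eSNP in any tissue.
#' @return list with `proportion_a` (gene list), `proportion_b` (universe),
#'   `z` and `p`.
#' @export
egene_enrichment <- function(genes, universe_genes, egene_set) {
  if (length(genes) == 0L || length(universe_genes) == 0L) {
    stopf("glucoMR_data_error", "empty gene list or universe")
  }
  if (!all(genes %in% universe_genes)) {
    stopf("glucoMR_data_error", "genes must be a subset of the universe")
  }
  x1 <- sum(genes %in% egene_set)
  x2 <- sum(universe_genes %in% egene_set)
  res <- two_prop_z(x1, length(genes), x2, length(universe_genes),
                    alternative = "two.sided")
  list(proportion_a = res$prop1, proportion_b = res$prop2, z = res$z,
       p = res$p)
}

#' GWAS enrichment summary for an eSNP set
#'
#' Matches the eSNP set to the GWAS by (case-normalized) SNP id, then
#' summarizes the association p-values of the matched SNPs: proportion
#' below `alpha`, BH FDR within the set, Bonferroni threshold alpha/n,
#' genomic-control inflation lambda_GC = median(qchisq(1-p, 1)) / 0.45494,
#' and QQ points against the uniform expectation.
#'
#' @param esnps character vector of SNP ids.
#' @param gwas GWAS table (snp_id, ..., pvalue).
#' @param alpha nominal threshold (default 0.05).
#' @return object of class `enrichment_summary`: list with `n_esnps`,
#'   `proportion_small_p`, `bh_q` (named), `bh_min_q`, `n_bh_hits`,
#'   `bonferroni_threshold`, `n_bonferroni_hits`, `lambda_gc`, `qq`
#'   (data frame expected/observed on the -log10 scale), `n_unmatched`.
#' @export
gwas_enrichment <- function(esnps, gwas, alpha = 0.05) {
  check_prob(alpha, "alpha")
  if (length(esnps) == 0L) stopf("glucoMR_data_error", "empty eSNP set")
  idx <- match(toupper(esnps), toupper(gwas$snp_id))
  unmatched <- esnps[is.na(idx)]
  if (length(unmatched) == length(esnps)) {
    stopf("glucoMR_data_error",
          "no eSNP found in the GWAS table; first unmatched ids: %s",
          paste(utils::head(unmatched, 5), collapse = ", "))
  }
  if (length(unmatched) > 0) {
    log_msg("info", "%d of %d eSNPs not in GWAS; skipped", length(unmatched),
            length(esnps))
  }
  p <- gwas$pvalue[idx[!is.na(idx)]]
  names(p) <- gwas$snp_id[idx[!is.na(idx)]]
  n <- length(p)
  q <- bh_adjust(p)
  chisq <- stats::qchisq(1 - p, df = 1)
  lambda_gc <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  ord <- order(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(p[ord]),
                   snp_id = names(p)[ord], row.names = NULL,
                   stringsAsFactors = FALSE)
  structure(list(
    n_esnps = n,
    proportion_small_p = mean(p < alpha),
    bh_q = q,
    bh_min_q = min(q),
    n_bh_hits = sum(q < 0.05),
    bonferroni_threshold = alpha / n,
    n_bonferroni_hits = sum(p < alpha / n),
    lambda_gc = lambda_gc,
    qq = qq,
    n_unmatched = length(unmatched)
  ), class = "enrichment_summary")
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf("<enrichment_summary> %d eSNPs; prop(p<alpha) = %.4f; lambda_GC = %.3f\n",
              x$n_esnps, x$proportion_small_p, x$lambda_gc))
  cat(sprintf("  BH hits (q<0.05): %d; Bonferroni threshold %.2e (%d hits)\n",
              x$n_bh_hits, x$bonferroni_threshold, x$n_bonferroni_hits))
  invisible(x)
}

#' Random-eGene permutation null for GWAS enrichment
#'
#' Repeatedly samples `k_genes` eGenes (genes with at least one significant
#' eSNP in any tissue) without replacement, collects their eSNPs, and
#' computes the enrichment statistic: the proportion of GWAS p-values below
#' `alpha` (default) or the number of BH q-values below 0.05. The empirical
#' p-value is add-one smoothed: (1 + #\{perm >= observed\}) / (1 + B).
#'
#' @param observed_stat statistic of the observed gene set.
#' @param k_genes number of genes per random draw.
#' @param eqtl eQTL table.
#' @param gwas GWAS table.
#' @param B number of permutations (>= 100; default 10000).
#' @param statistic "proportion_small_p" or "bh_hits".
#' @param alpha nominal GWAS threshold for "proportion_small_p".
#' @param fdr_max eQTL significance threshold defining eSNPs/eGenes.
#' @param seed RNG seed.
#' @return list with `p`, `perm_stats`, `statistic`, `B`, `k_genes`,
#'   `n_egenes`.
#' @export
permutation_enrichment <- function(observed_stat, k_genes, eqtl, gwas,
                                   B = 10000L,
                                   statistic = c("proportion_small_p",
                                                 "bh_hits"),
                                   alpha = 0.05, fdr_max = 0.05,
                                   seed = NULL) {
  statistic <- match.arg(statistic)
  if (B < 100L) stopf("glucoMR_parameter_error", "B must be >= 100")
  sig <- eqtl[eqtl$fdr <= fdr_max, c("gene_id", "snp_id")]
  snp_by_gene <- split(sig$snp_id, sig$gene_id)
  snp_by_gene <- lapply(snp_by_gene, unique)
  egenes <- names(snp_by_gene)
  if (length(egenes) < k_genes) {
    stopf("glucoMR_data_error", "eGene universe (%d) smaller than k_genes (%d)",
          length(egenes), k_genes)
  }
  pv <- gwas$pvalue
  names(pv) <- toupper(gwas$snp_id)
  stat_of <- function(snps) {
    p <- pv[toupper(snps)]
    p <- p[!is.na(p)]
    if (length(p) == 0L) return(NA_real_)
    if (statistic == "proportion_small_p") mean(p < alpha)
    else sum(bh_adjust(p) < 0.05)
  }
  perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      g <- sample(egenes, k_genes)
      stat_of(unique(unlist(snp_by_gene[g], use.names = FALSE)))
    }, numeric(1))
  })
  perm_ok <- perm[!is.na(perm)]
  p_emp <- (1 + sum(perm_ok >= observed_stat)) / (1 + length(perm_ok))
  list(p = p_emp, perm_stats = perm, statistic = statistic, B = B,
       k_genes = k_genes, n_egenes = length(egenes))
}

#' Compare small-p fractions between two p-value sets
#'
#' One-sided two-proportion z-test that the fraction of p-values below
#' `alpha` in set A exceeds that in set B.
#'
#' @param set_a_pvalues,set_b_pvalues numeric p-value vectors.
#' @param alpha nominal threshold (default 0.05).
#' @return list with `z`, `p`, `proportion_a`, `proportion_b`.
#' @export
compare_proportions <- function(set_a_pvalues, set_b_pvalues, alpha = 0.05) {
  check_prob(alpha, "alpha")
  if (length(set_a_pvalues) == 0L || length(set_b_pvalues) == 0L) {
    stopf("glucoMR_data_error", "both p-value sets must be nonempty")
  }
  res <- two_prop_z(sum(set_a_pvalues < alpha), length(set_a_pvalues),
                    sum(set_b_pvalues < alpha), length(set_b_pvalues),
                    alternative = "greater")
  list(z = res$z, p = res$p, proportion_a = res$prop1,
       proportion_b = res$prop2)
}
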