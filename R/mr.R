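# Summary-data Mendelian randomization: SMR effect and chi-square test,
# HEIDI horizontal-pleiotropy test, multi-SNP SMR with an LD-aware null,
# plus LD computation from a reference panel, greedy pruning (r^2 < 0.2)
# and proxy lookup (r^2 > 0.8).

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize eQTL and GWAS summary rows into an instrument table
#'
#' Joins on SNP id; when both tables carry allele columns, the GWAS effect
#' is flipped where effect/other alleles are swapped, and strand-ambiguous
#' (A/T, C/G) SNPs are dropped with a log entry. Without allele columns the
#' tables are assumed pre-aligned.
#'
#' @param eqtl_rows data frame with snp_id, beta, se, pvalue (the exposure,
#'   b_zx) and optionally effect_allele/other_allele.
#' @param gwas_rows data frame with snp_id, beta, se, pvalue (the outcome,
#'   b_zy) and optionally effect_allele/other_allele.
#' @return data frame of class `instrument_table` with snp_id, b_zx, se_zx,
#'   p_zx, b_zy, se_zy, p_zy, harmonized; attribute `n_dropped_ambiguous`.
#' @export
harmonize <- function(eqtl_rows, gwas_rows) {
  common <- intersect(eqtl_rows$snp_id, gwas_rows$snp_id)
  if (length(common) == 0L) {
    stopf("glucoMR_data_error", "no shared SNP ids between eQTL and GWAS rows")
  }
  e <- eqtl_rows[match(common, eqtl_rows$snp_id), ]
  g <- gwas_rows[match(common, gwas_rows$snp_id), ]
  flip <- rep(FALSE, length(common))
  drop <- rep(FALSE, length(common))
  have_alleles <- all(c("effect_allele", "other_allele") %in% names(e)) &&
    all(c("effect_allele", "other_allele") %in% names(g))
  if (have_alleles) {
    pair_g <- toupper(paste(g$effect_allele, g$other_allele, sep = "/"))
    drop <- pair_g %in% STRAND_AMBIGUOUS |
      toupper(paste(e$effect_allele, e$other_allele, sep = "/")) %in%
        STRAND_AMBIGUOUS
    same <- toupper(e$effect_allele) == toupper(g$effect_allele) &
      toupper(e$other_allele) == toupper(g$other_allele)
    swapped <- toupper(e$effect_allele) == toupper(g$other_allele) &
      toupper(e$other_allele) == toupper(g$effect_allele)
    flip <- swapped & !drop
    drop <- drop | (!same & !swapped)
  }
  if (any(drop)) {
    log_msg("info", "harmonize: dropped %d SNP(s) (strand-ambiguous or allele mismatch)",
            sum(drop))
  }
  out <- data.frame(
    snp_id = common,
    b_zx = e$beta, se_zx = e$se, p_zx = e$pvalue,
    b_zy = ifelse(flip, -g$beta, g$beta), se_zy = g$se, p_zy = g$pvalue,
    harmonized = TRUE, stringsAsFactors = FALSE)[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_ambiguous") <- sum(drop)
  class(out) <- c("instrument_table", "data.frame")
  out
}

#' Signed LD correlation matrix from a reference panel
#'
#' Pearson correlation of dosages, with a small ridge folded in so the
#' matrix is positive semidefinite while keeping a unit diagonal.
#' Monomorphic SNPs are excluded with a warning.
#'
#' @param panel a `genotype_panel`.
#' @param snps SNP ids to include.
#' @param ridge ridge weight (default 1e-6).
#' @return correlation matrix with SNP ids as dimnames.
#' @export
compute_ld <- function(panel, snps, ridge = 1e-6) {
  stopifnot(inherits(panel, "genotype_panel"))
  missing <- setdiff(snps, colnames(panel$dosages))
  if (length(missing)) {
    stopf("glucoMR_data_error", "SNP(s) absent from panel: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  D <- panel$dosages[, snps, drop = FALSE]
  v <- apply(D, 2, stats::var)
  if (any(v == 0)) {
    warning(sprintf("excluding %d monomorphic SNP(s)", sum(v == 0)))
    D <- D[, v > 0, drop = FALSE]
  }
  if (ncol(D) == 0L) stopf("glucoMR_data_error", "no polymorphic SNP left")
  r <- stats::cor(D)
  (r + diag(ridge, ncol(r))) / (1 + ridge)
}

#' Greedy LD pruning of an instrument table
#'
#' Instruments are visited in order of increasing exposure p-value (ties by
#' SNP id); a SNP is accepted iff its r^2 with every previously accepted
#' SNP is below `r2_max`. Deterministic.
#'
#' @param instruments an `instrument_table`.
#' @param ld LD matrix covering the instruments (from [compute_ld()]).
#' @param r2_max pruning threshold (default 0.2).
#' @param verify exhaustively re-check that no retained pair reaches
#'   `r2_max` (debug guard).
#' @return the retained subset of `instruments`.
#' @export
prune_ld <- function(instruments, ld, r2_max = 0.2, verify = FALSE) {
  ids <- instruments$snp_id
  if (!all(ids %in% rownames(ld))) {
    stopf("glucoMR_data_error", "LD matrix does not cover all instruments")
  }
  ord <- order(instruments$p_zx, instruments$snp_id)
  kept <- character(0)
  for (i in ord) {
    s <- ids[i]
    if (all(ld[s, kept]^2 < r2_max)) kept <- c(kept, s)
  }
  if (verify) {
    if (length(kept) > 1L) {
      rr <- ld[kept, kept]^2
      diag(rr) <- 0
      stopifnot(all(rr < r2_max))
    }
  }
  out <- instruments[match(kept, ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Proxy SNPs in high LD with a query SNP
#'
#' @param snp query SNP id.
#' @param ld LD matrix.
#' @param r2_min proxy threshold (default 0.8, proxies have r^2 > r2_min).
#' @return data frame with snp_id and r2, sorted by decreasing r^2
#'   (self excluded).
#' @export
find_proxies <- function(snp, ld, r2_min = 0.8) {
  if (!snp %in% rownames(ld)) {
    stopf("glucoMR_data_error", "SNP '%s' not in LD matrix", snp)
  }
  r2 <- ld[snp, ]^2
  r2 <- r2[names(r2) != snp]
  hit <- r2[r2 > r2_min]
  hit <- sort(hit, decreasing = TRUE)
  data.frame(snp_id = names(hit), r2 = unname(hit), stringsAsFactors = FALSE)
}

#' Summary-data Mendelian randomization test for one instrument
#'
#' b_xy = b_zy / b_zx estimates the effect of a one-SD change in exposure
#' (expression) on the outcome. The test statistic is
#' T = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2), compared against chi-square with
#' 1 df; se_xy = |b_xy| / sqrt(T) when T > 0.
#'
#' @param instrument a single-row `instrument_table` (or a list with b_zx,
#'   se_zx, b_zy, se_zy).
#' @return object of class `smr_result`: list with `b_xy`, `se_xy`,
#'   `T_smr`, `p_smr`, `n_instruments`, `snp_id`.
#' @export
smr_test <- function(instrument) {
  if (is.data.frame(instrument)) {
    if (nrow(instrument) != 1L) {
      stopf("glucoMR_parameter_error",
            "smr_test takes a single instrument; use multi_snp_smr for several")
    }
    instrument <- as.list(instrument)
  }
  if (instrument$b_zx == 0) {
    stopf("glucoMR_weak_instrument_error", "b_zx is zero (no exposure effect)")
  }
  z1 <- instrument$b_zx / instrument$se_zx
  z2 <- instrument$b_zy / instrument$se_zy
  b_xy <- instrument$b_zy / instrument$b_zx
  T_smr <- if (z1 == 0 && z2 == 0) 0 else (z1^2 * z2^2) / (z1^2 + z2^2)
  p <- stats::pchisq(T_smr, df = 1, lower.tail = FALSE)
  se_xy <- if (T_smr > 0) abs(b_xy) / sqrt(T_smr) else NA_real_
  structure(list(b_xy = b_xy, se_xy = se_xy, T_smr = T_smr, p_smr = p,
                 n_instruments = 1L,
                 snp_id = if (!is.null(instrument$snp_id)) instrument$snp_id
                          else NA_character_),
            class = "smr_result")
}

#' @export
print.smr_result <- function(x, ...) {
  cat(sprintf("<smr_result> b_xy = %.4f (se %.4f), T = %.3f, p = %.3g [%s]\n",
              x$b_xy, x$se_xy, x$T_smr, x$p_smr, x$snp_id))
  invisible(x)
}

# Delta-method covariance of the per-SNP b_xy estimates. b_zx and b_zy come
# from non-overlapping samples, so they are independent of each other;
# across SNPs each correlates through LD r_ij.
bxy_covariance <- function(inst, ld) {
  ids <- inst$snp_id
  r <- ld[ids, ids, drop = FALSE]
  inv_bzx <- 1 / inst$b_zx
  gy <- inv_bzx                       # d b_xy / d b_zy
  gx <- -inst$b_zy * inv_bzx^2        # d b_xy / d b_zx
  r * (outer(gy * inst$se_zy, gy * inst$se_zy) +
         outer(gx * inst$se_zx, gx * inst$se_zx))
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Rejection indicates that the per-SNP b_xy estimates at the locus are too
#' heterogeneous to reflect a single causal variant acting through the
#' exposure, i.e. horizontal pleiotropy or linkage. The top SNP is the
#' smallest exposure p-value; for every other retained instrument the
#' difference d_i = b_xy_i - b_xy_top is standardized using first-order
#' error propagation with LD-induced correlations, and T = sum z_d^2 is
#' compared against the matched-moments (Satterthwaite) approximation of
#' the weighted chi-square null with weights from the correlation matrix of
#' the d's.
#'
#' @param instruments an `instrument_table`.
#' @param ld LD matrix covering the instruments.
#' @param p_zx_max exposure significance required for inclusion
#'   (default 1.6e-3).
#' @param max_snps cap on instruments, keeping the smallest exposure
#'   p-values (default 20).
#' @param r2_window keep SNPs whose r^2 with the top SNP lies inside this
#'   window (default c(0.05, 0.9)).
#' @return list with `T_heidi`, `p`, `n_used`, `top_snp`, `testable`.
#' @export
heidi_test <- function(instruments, ld, p_zx_max = 1.6e-3, max_snps = 20L,
                       r2_window = c(0.05, 0.9)) {
  inst <- instruments[order(instruments$p_zx, instruments$snp_id), ,
                      drop = FALSE]
  top <- inst$snp_id[1]
  r2_top <- ld[top, inst$snp_id]^2
  keep <- inst$p_zx < p_zx_max &
    (inst$snp_id == top |
       (r2_top >= r2_window[1] & r2_top <= r2_window[2]))
  inst <- inst[keep, , drop = FALSE]
  if (nrow(inst) > max_snps) inst <- inst[seq_len(max_snps), , drop = FALSE]
  if (nrow(inst) < 3L) {
    return(list(T_heidi = NA_real_, p = NA_real_, n_used = nrow(inst),
                top_snp = top, testable = FALSE))
  }
  C <- bxy_covariance(inst, ld)
  b_xy <- inst$b_zy / inst$b_zx
  it <- 1L  # top SNP sits first after the p_zx sort
  d <- b_xy[-it] - b_xy[it]
  V <- C[-it, -it, drop = FALSE] -
    matrix(C[-it, it], nrow(C) - 1L, nrow(C) - 1L) -
    t(matrix(C[-it, it], nrow(C) - 1L, nrow(C) - 1L)) + C[it, it]
  sd_d <- sqrt(diag(V))
  z_d <- d / sd_d
  T_heidi <- sum(z_d^2)
  Rho <- V / outer(sd_d, sd_d)
  lambda <- eigen(Rho, symmetric = TRUE, only.values = TRUE)$values
  p <- satterthwaite_p(T_heidi, pmax(lambda, 0))
  list(T_heidi = T_heidi, p = p, n_used = nrow(inst), top_snp = top,
       testable = TRUE)
}

#' Multi-SNP SMR over LD-pruned instruments
#'
#' Sums the per-instrument SMR chi-square statistics; the null is the
#' weighted chi-square with weights equal to the eigenvalues of the
#' instruments' squared-LD (r^2) matrix (both z_zx and z_zy correlate
#' through r across SNPs), evaluated by Satterthwaite moment matching.
#' With independent instruments this reduces to chi-square with m df.
#'
#' @param instruments_pruned an `instrument_table` pruned to r^2 < 0.2
#'   (see [prune_ld()]).
#' @param ld LD matrix covering the instruments.
#' @return list with `T_multi`, `p`, `n_instruments`, `per_snp_T`. A single
#'   instrument falls back to [smr_test()] with a notice.
#' @export
multi_snp_smr <- function(instruments_pruned, ld) {
  m <- nrow(instruments_pruned)
  if (m == 0L) stopf("glucoMR_data_error", "no instruments")
  if (m == 1L) {
    log_msg("info", "single instrument: falling back to smr_test")
    s <- smr_test(instruments_pruned)
    return(list(T_multi = s$T_smr, p = s$p_smr, n_instruments = 1L,
                per_snp_T = stats::setNames(s$T_smr, s$snp_id)))
  }
  Ti <- vapply(seq_len(m), function(i)
    smr_test(instruments_pruned[i, , drop = FALSE])$T_smr, numeric(1))
  A <- ld[instruments_pruned$snp_id, instruments_pruned$snp_id]^2
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  T_multi <- sum(Ti)
  p <- satterthwaite_p(T_multi, pmax(lambda, 0))
  list(T_multi = T_multi, p = p, n_instruments = m,
       per_snp_T = stats::setNames(Ti, instruments_pruned$snp_id))
}
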