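# Shared fixtures and independent oracles used across test files.

# small simulation world for fast end-to-end tests
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_genes = 200L, n_snps = 150L, n_response_genes = 44L,
    n_diff_response_genes = 6L, n_cases = 300L, n_controls = 600L,
    n_ref = 300L, n_eqtl_samples = 300L, seed = seed), list(...))
  do.call(sim_config, args)
}

# hand-built expression matrix: `hg` and `sg` are gene x (individual x
# replicate) value arrays supplied as lists of per-individual matrices
make_expr <- function(values, individuals, replicates, conditions, groups) {
  samples <- data.frame(
    sample_id = colnames(values), individual = individuals,
    replicate = replicates, condition = conditions, group = groups,
    stringsAsFactors = FALSE)
  expression_matrix(values, samples)
}

# fully crossed layout helper: n_ind individuals x n_rep replicates x SG/HG
layout_values <- function(n_genes, n_ind, n_rep, fill) {
  inds <- sprintf("i%02d", seq_len(n_ind))
  grid <- expand.grid(replicate = seq_len(n_rep), condition = c("SG", "HG"),
                      individual = inds, stringsAsFactors = FALSE)
  grid$sample_id <- with(grid, paste(individual, condition, replicate, sep = "_"))
  vals <- matrix(fill, n_genes, nrow(grid),
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                 grid$sample_id))
  list(values = vals, grid = grid)
}

# brute-force Subramanian running sum, written independently of the
# package implementation (explicit loop, no shared code paths)
brute_es <- function(gene_ids, scores, gene_set, weight = 1) {
  N <- length(gene_ids)
  hits <- gene_ids %in% gene_set
  nh <- sum(hits)
  nr <- sum(abs(scores[hits])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + abs(scores[i])^weight / nr
    } else {
      run <- run - 1 / (N - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Compare an ES against the brute-force oracle. When the running sum has a
# positive and a negative extreme of equal magnitude (to within float
# epsilon), the two implementations may legitimately pick opposite signs
# because their summation orders round differently; accept either side of
# such an exact tie.
expect_es_match <- function(es, brute) {
  ok <- abs(es - brute) < 1e-12 ||
    (abs(abs(es) - abs(brute)) < 1e-9 && abs(es + brute) < 1e-9)
  expect_true(ok, label = sprintf("ES %.15f vs oracle %.15f", es, brute))
}

# closed-form two-proportion z-test (independent of the package helper)
oracle_two_prop <- function(x1, n1, x2, n2, one_sided = FALSE) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (one_sided) pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
}

# instrument table builder
make_instruments <- function(snp_id, b_zx, se_zx, b_zy, se_zy,
                             p_zx = 2 * pnorm(-abs(b_zx / se_zx))) {
  structure(data.frame(snp_id = snp_id, b_zx = b_zx, se_zx = se_zx,
                       p_zx = p_zx, b_zy = b_zy, se_zy = se_zy,
                       p_zy = 2 * pnorm(-abs(b_zy / se_zy)),
                       harmonized = TRUE, stringsAsFactors = FALSE),
            class = c("instrument_table", "data.frame"))
}

# one-locus summary-statistic simulation through the package generator;
# returns harmonized instruments plus the LD matrix and truth
simulate_locus <- function(seed, n_snps = 20L, ld_rho = 0.8,
                           mediation = 0.15, pleiotropy = 0,
                           eqtl_beta_sd = 0.4, n_eqtl = 500L,
                           n_cases = 300L, n_controls = 600L) {
  cfg <- sim_config(n_genes = 2L, n_snps = n_snps, n_response_genes = 1L,
                    n_diff_response_genes = 1L, ld_rho = ld_rho,
                    eqtl_effect_sd = eqtl_beta_sd,
                    mediation_effect = mediation,
                    pleiotropy_effect = pleiotropy,
                    n_cases = n_cases, n_controls = n_controls,
                    n_ref = 300L, n_eqtl_samples = n_eqtl,
                    cis_window_snps = n_snps, gwas_model = "liability",
                    seed = seed)
  panel <- simulate_reference_panel(cfg)
  st <- simulate_expression_study(cfg, panel)
  ss <- simulate_summary_statistics(cfg, panel, st$truth)
  gene <- st$truth$diff_response_genes[1]
  rows <- ss$eqtl[ss$eqtl$gene_id == gene, ]
  inst <- harmonize(rows, ss$gwas)
  ld <- suppressWarnings(compute_ld(panel, inst$snp_id))
  inst <- inst[inst$snp_id %in% rownames(ld), , drop = FALSE]
  list(inst = inst, ld = ld, truth = st$truth, config = cfg)
}
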