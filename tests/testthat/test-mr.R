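# Summary-data MR: harmonization, LD, pruning, proxies, SMR, HEIDI,
# multi-SNP SMR.

test_that("harmonize: allele alignment rules on a 5-SNP fixture", {
  eq <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(0.5, 0.4, 0.3, 0.2, 0.1), se = 0.1, pvalue = 1e-4,
                   effect_allele = c("A", "A", "A", "C", "A"),
                   other_allele = c("G", "G", "T", "T", "G"),
                   stringsAsFactors = FALSE)
  gw <- data.frame(snp_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   beta = c(0.10, 0.12, 0.14, 0.16, 0.18), se = 0.05,
                   pvalue = 0.01,
                   effect_allele = c("A", "G", "A", "C", "T"),
                   other_allele = c("G", "A", "T", "T", "C"),
                   stringsAsFactors = FALSE)
  inst <- harmonize(eq, gw)
  # rs3 is A/T ambiguous (dropped); rs5 allele mismatch (dropped); 3 retained
  expect_equal(nrow(inst), 3)
  expect_equal(attr(inst, "n_dropped_ambiguous"), 2)
  expect_equal(inst$b_zy[inst$snp_id == "rs1"], 0.10)    # same alleles
  expect_equal(inst$b_zy[inst$snp_id == "rs2"], -0.12)   # swapped -> flipped
  expect_equal(inst$b_zy[inst$snp_id == "rs4"], 0.16)
  expect_error(harmonize(eq, data.frame(snp_id = "zz", beta = 1, se = 1,
                                        pvalue = 1)),
               class = "glucoMR_data_error")
  # without allele columns the join is positional on snp_id, no flips
  plain <- harmonize(eq[, 1:4], gw[, 1:4])
  expect_equal(nrow(plain), 5)
  expect_equal(plain$b_zy, gw$beta)
})

test_that("compute_ld matches hand-computed Pearson r", {
  dos <- matrix(c(0, 1, 2, 1, 0, 2,
                  0, 1, 2, 1, 0, 2,   # duplicate column -> r = 1
                  2, 1, 0, 1, 2, 0,
                  1, 1, 1, 1, 1, 1),  # monomorphic
                nrow = 6)
  colnames(dos) <- c("s1", "s2", "s3", "s4")
  rownames(dos) <- sprintf("i%d", 1:6)
  panel <- structure(list(dosages = dos, snp_ids = colnames(dos),
                          allele_freqs = colMeans(dos) / 2, ld_rho = NA),
                     class = "genotype_panel")
  expect_warning(ld <- compute_ld(panel, c("s1", "s2", "s3", "s4")),
                 "monomorphic")
  expect_false("s4" %in% rownames(ld))
  expect_equal(ld["s1", "s1"], 1, tolerance = 1e-9)
  expect_equal(ld["s1", "s2"], cor(dos[, 1], dos[, 2]), tolerance = 1e-6)
  expect_equal(ld["s1", "s3"], cor(dos[, 1], dos[, 3]), tolerance = 1e-6)
  # hand Pearson on the anti-correlated pair
  expect_equal(unname(cor(dos[, 1], dos[, 3])), -1)
  expect_error(compute_ld(panel, "missing"), class = "glucoMR_data_error")
})

test_that("prune_ld: degenerate cases and exhaustive verification", {
  inst <- make_instruments(sprintf("s%d", 1:3), b_zx = c(0.5, 0.4, 0.3),
                           se_zx = 0.1, b_zy = 0.1, se_zy = 0.05,
                           p_zx = c(1e-8, 1e-6, 1e-4))
  ld_ind <- diag(3); dimnames(ld_ind) <- list(inst$snp_id, inst$snp_id)
  expect_equal(nrow(prune_ld(inst, ld_ind)), 3)
  ld_all <- matrix(1, 3, 3, dimnames = dimnames(ld_ind))
  kept <- prune_ld(inst, ld_all)
  expect_equal(kept$snp_id, "s1")   # smallest p_zx wins
  # random panels: retained set never contains a pair with r^2 >= 0.2
  for (s in 1:50) {
    cfg <- tiny_config(seed = 600 + s, n_snps = 12L, n_ref = 80L,
                       ld_rho = runif(1, 0, 0.95))
    panel <- simulate_reference_panel(cfg)
    ld <- suppressWarnings(compute_ld(panel, panel$snp_ids))
    ids <- rownames(ld)
    inst <- make_instruments(ids, b_zx = rnorm(length(ids), 0, 0.3),
                             se_zx = 0.05, b_zy = 0, se_zy = 0.05)
    kept <- prune_ld(inst, ld, r2_max = 0.2, verify = TRUE)
    if (nrow(kept) > 1) {
      rr <- ld[kept$snp_id, kept$snp_id]^2
      diag(rr) <- 0
      expect_lt(max(rr), 0.2)
    }
  }
})

test_that("find_proxies: self excluded, independence, planted duplicate", {
  ld <- diag(3)
  dimnames(ld) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(nrow(find_proxies("a", ld)), 0)
  ld["a", "b"] <- ld["b", "a"] <- 1       # duplicate column
  ld["a", "c"] <- ld["c", "a"] <- 0.5
  got <- find_proxies("a", ld)
  expect_equal(got$snp_id, "b")
  expect_equal(got$r2, 1)
  expect_error(find_proxies("zz", ld), class = "glucoMR_data_error")
})

test_that("smr_test: worked example, null outcome, equivariances", {
  s <- smr_test(list(snp_id = "rs1", b_zx = 0.5, se_zx = 0.1,
                     b_zy = 0.06, se_zy = 0.02))
  expect_equal(s$b_xy, 0.12, tolerance = 1e-12)
  expect_equal(s$T_smr, 225 / 34, tolerance = 1e-12)
  expect_equal(s$p_smr, pchisq(225 / 34, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(s$se_xy, 0.12 / sqrt(225 / 34), tolerance = 1e-4)

  s0 <- smr_test(list(b_zx = 0.5, se_zx = 0.1, b_zy = 0, se_zy = 0.02))
  expect_equal(s0$b_xy, 0)
  expect_equal(s0$T_smr, 0)
  expect_equal(s0$p_smr, 1)
  expect_true(is.na(s0$se_xy))

  # scaling the outcome by c scales b_xy but not T or p
  sc <- smr_test(list(b_zx = 0.5, se_zx = 0.1, b_zy = 0.18, se_zy = 0.06))
  expect_equal(sc$b_xy, 3 * s$b_xy, tolerance = 1e-12)
  expect_equal(sc$T_smr, s$T_smr, tolerance = 1e-12)
  # simultaneous sign flip leaves p unchanged
  sf <- smr_test(list(b_zx = -0.5, se_zx = 0.1, b_zy = -0.06, se_zy = 0.02))
  expect_equal(sf$p_smr, s$p_smr, tolerance = 1e-12)
  expect_equal(sf$b_xy, s$b_xy, tolerance = 1e-12)

  expect_error(smr_test(list(b_zx = 0, se_zx = 0.1, b_zy = 1, se_zy = 1)),
               class = "glucoMR_weak_instrument_error")
})

test_that("heidi_test: perfect homogeneity and non-testable inputs", {
  # identical b_xy across independent noise-free instruments -> T = 0, p = 1
  inst <- make_instruments(sprintf("s%d", 1:5),
                           b_zx = c(0.5, 0.45, 0.4, 0.35, 0.3),
                           se_zx = 1e-4,
                           b_zy = 0.2 * c(0.5, 0.45, 0.4, 0.35, 0.3),
                           se_zy = 1e-4)
  ld <- diag(5) * 0.7 + 0.3   # uniform LD inside the [0.05, 0.9] r^2 window
  dimnames(ld) <- list(inst$snp_id, inst$snp_id)
  got <- heidi_test(inst, ld)
  expect_true(got$testable)
  expect_lt(got$T_heidi, 1e-6)
  expect_gt(got$p, 0.999)
  # fewer than 3 usable instruments: a result object, not an exception
  weak <- make_instruments(c("a", "b"), b_zx = c(0.5, 0.4), se_zx = 0.1,
                           b_zy = 0.1, se_zy = 0.05)
  ld2 <- diag(2); dimnames(ld2) <- list(c("a", "b"), c("a", "b"))
  nt <- heidi_test(weak, ld2)
  expect_false(nt$testable)
  expect_true(is.na(nt$p))
})

test_that("multi_snp_smr: independent instruments give the chi-square_m null", {
  # strong instruments, independent: T_multi ~ chi^2_m; the Satterthwaite
  # weights are all 1 so the reported p is the analytic chi-square tail
  m <- 5
  inst <- make_instruments(sprintf("s%d", 1:m), b_zx = 1, se_zx = 0.01,
                           b_zy = c(0.02, -0.01, 0.015, 0, 0.01),
                           se_zy = 0.01)
  ld <- diag(m); dimnames(ld) <- list(inst$snp_id, inst$snp_id)
  got <- multi_snp_smr(inst, ld)
  expect_equal(got$n_instruments, m)
  expect_equal(got$p, pchisq(got$T_multi, df = m, lower.tail = FALSE),
               tolerance = 1e-9)
  # all T = 0 -> p = 1
  null_inst <- make_instruments(sprintf("s%d", 1:3), b_zx = 0.5, se_zx = 0.1,
                                b_zy = 0, se_zy = 0.05)
  ld3 <- diag(3); dimnames(ld3) <- list(null_inst$snp_id, null_inst$snp_id)
  expect_equal(multi_snp_smr(null_inst, ld3)$p, 1)
  # single instrument falls back to smr_test
  one <- multi_snp_smr(null_inst[1, ], ld3)
  expect_equal(one$n_instruments, 1)
  expect_equal(one$T_multi, smr_test(null_inst[1, ])$T_smr)
})

test_that("multi-SNP SMR is powered under mediation and quiet under the null", {
  # with a single causal eQTL per gene the top-SNP test concentrates the
  # signal, so aggregation is not guaranteed to sharpen it; the defensible
  # property is power against the mediated alternative vs the null world
  run_multi <- function(seed, mediation) {
    loc <- simulate_locus(seed = seed, n_snps = 25L, ld_rho = 0.6,
                          mediation = mediation, eqtl_beta_sd = 0.5)
    inst <- loc$inst[loc$inst$p_zx < 1e-3, , drop = FALSE]
    if (nrow(inst) < 2) return(NA)
    pruned <- prune_ld(inst, loc$ld, 0.2)
    if (nrow(pruned) < 2) return(NA)
    multi_snp_smr(pruned, loc$ld)$p
  }
  p_alt <- sapply(1:40, function(s) run_multi(7000 + s, 0.3))
  p_null <- sapply(1:40, function(s) run_multi(7500 + s, 0))
  expect_gt(mean(p_alt < 0.05, na.rm = TRUE), 0.5)
  expect_lt(mean(p_null < 0.05, na.rm = TRUE), 0.2)
})
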