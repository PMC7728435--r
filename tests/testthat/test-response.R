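# Expression-response module: detection filter, response matrix,
# empirical-Bayes moderation, differential tests, QC analyses.

test_that("detection filter keeps the hand-counted genes", {
  lv <- layout_values(10, 2, 2, fill = 8)
  dp <- matrix(0, 10, ncol(lv$values), dimnames = dimnames(lv$values))
  # genes 8..10 detected in fewer than half of the 8 samples
  dp[8:10, ] <- 1
  dp[8, 1:3] <- 0
  expr <- expression_matrix(lv$values, data.frame(
    sample_id = lv$grid$sample_id, individual = lv$grid$individual,
    replicate = lv$grid$replicate, condition = lv$grid$condition,
    group = "nDM", stringsAsFactors = FALSE), detection_p = dp)
  expect_equal(nrow(filter_detected_genes(expr, 0.01, 0.5)$values), 7)
  # pass-all and pass-none
  dp0 <- dp; dp0[] <- 0
  expr$detection_p <- dp0
  expect_equal(nrow(filter_detected_genes(expr)$values), 10)
  dp1 <- dp; dp1[] <- 1
  expr$detection_p <- dp1
  expect_equal(nrow(filter_detected_genes(expr)$values), 0)
  # bad alpha; missing detection matrix passes through with warning
  expect_error(filter_detected_genes(expr, alpha = 2),
               class = "glucoMR_parameter_error")
  expr$detection_p <- NULL
  expect_warning(out <- filter_detected_genes(expr), "no detection")
  expect_equal(nrow(out$values), 10)
})

test_that("compute_response: hand arithmetic, symmetry, dropped individuals", {
  lv <- layout_values(1, 2, 2, fill = 0)
  v <- lv$values
  v[1, ] <- c(10.0, 10.2, 10.6, 10.8,   # i01: SG r1 r2, HG r1 r2
              5.0, 5.0, 5.0, 5.0)       # i02: flat
  expr <- make_expr(v, lv$grid$individual, lv$grid$replicate,
                    lv$grid$condition, rep("nDR", 8))
  resp <- compute_response(expr)
  expect_equal(unname(resp$delta[1, "i01"]), 0.6)
  expect_equal(unname(resp$delta[1, "i02"]), 0)
  # permuting replicate order leaves delta unchanged
  perm <- c(2, 1, 4, 3, 6, 5, 8, 7)
  expr2 <- make_expr(v[, perm, drop = FALSE], lv$grid$individual[perm],
                     lv$grid$replicate[perm], lv$grid$condition[perm],
                     rep("nDR", 8))
  expect_equal(compute_response(expr2)$delta, resp$delta)
  # an individual missing HG is dropped; none left -> error
  keep <- lv$grid$individual == "i01" | lv$grid$condition == "SG"
  expr3 <- make_expr(v[, keep, drop = FALSE], lv$grid$individual[keep],
                     lv$grid$replicate[keep], lv$grid$condition[keep],
                     rep("nDR", sum(keep)))
  expect_equal(colnames(compute_response(expr3)$delta), "i01")
  only_sg <- lv$grid$condition == "SG"
  expr4 <- make_expr(v[, only_sg, drop = FALSE], lv$grid$individual[only_sg],
                     lv$grid$replicate[only_sg], lv$grid$condition[only_sg],
                     rep("nDR", sum(only_sg)))
  expect_error(compute_response(expr4), class = "glucoMR_data_error")
})

test_that("moderation prior: equal variances, recovery of d0, errors", {
  pr <- fit_moderation_prior(rep(2.5, 100), residual_df = 10)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_sq, 2.5, tolerance = 1e-6)

  # parameter recovery from the generating scaled-inverse-chi-square prior
  set.seed(42)
  d0_true <- 4; s0 <- 1; df <- 10
  sigma2 <- d0_true * s0 / rchisq(5000, df = d0_true)
  s2 <- sigma2 * rchisq(5000, df = df) / df
  pr <- fit_moderation_prior(s2, residual_df = df)
  expect_lt(abs(pr$d0 - d0_true) / d0_true, 0.2)
  expect_lt(abs(pr$s0_sq - s0) / s0, 0.2)

  expect_error(fit_moderation_prior(rep(0, 50), 10),
               class = "glucoMR_degenerate_error")
  expect_error(fit_moderation_prior(rep(1, 50), -1),
               class = "glucoMR_parameter_error")
})

test_that("moderation agrees with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(1)
  s2 <- 0.5 * rchisq(2000, df = 8) / 8 * (4 / rchisq(2000, df = 4))
  pr <- fit_moderation_prior(s2, residual_df = 8)
  sq <- limma::squeezeVar(s2, df = 8)
  expect_lt(abs(pr$d0 - sq$df.prior) / sq$df.prior, 0.05)
  expect_lt(abs(pr$s0_sq - sq$var.prior) / sq$var.prior, 0.05)
  post <- (pr$d0 * pr$s0_sq + 8 * s2) / (pr$d0 + 8)
  expect_lt(max(abs(post - sq$var.post) / sq$var.post), 0.05)
})

test_that("moderated t: d0=0 gives the classical t; d0=Inf the closed form", {
  set.seed(7)
  n <- 9
  delta <- matrix(rnorm(500 * n), 500, n,
                  dimnames = list(sprintf("g%03d", 1:500),
                                  sprintf("i%02d", 1:n)))
  resp <- structure(list(delta = delta,
                         groups = setNames(rep("nDR", n), colnames(delta))),
                    class = "response_matrix")
  pr0 <- structure(list(d0 = 0, s0_sq = 1), class = "moderation_prior")
  got <- test_response_all(resp, pr0)
  classical_t <- rowMeans(delta) / (apply(delta, 1, sd) / sqrt(n))
  expect_lt(max(abs(got$t - unname(classical_t))), 1e-10)
  expect_equal(got$pvalue, unname(2 * pt(-abs(classical_t), n - 1)),
               tolerance = 1e-12)

  prI <- structure(list(d0 = Inf, s0_sq = 0.5), class = "moderation_prior")
  gotI <- test_response_all(resp, prI)
  expect_equal(gotI$t, unname(rowMeans(delta) * sqrt(n) / sqrt(0.5)),
               tolerance = 1e-12)
})

test_that("zero-variance genes stay finite under a finite prior", {
  delta <- matrix(0.3, 20, 6, dimnames = list(sprintf("g%d", 1:20),
                                              sprintf("i%d", 1:6)))
  resp <- structure(list(delta = delta,
                         groups = setNames(rep("nDR", 6), colnames(delta))),
                    class = "response_matrix")
  pr <- structure(list(d0 = 4, s0_sq = 0.1), class = "moderation_prior")
  got <- test_response_all(resp, pr)
  expect_true(all(is.finite(got$t)) && all(got$t > 0))
})

test_that("one-sample null calibration and BH monotonicity", {
  set.seed(11)
  n <- 10
  delta <- matrix(rnorm(10000 * n), 10000, n,
                  dimnames = list(sprintf("g%05d", 1:10000),
                                  sprintf("i%02d", 1:n)))
  resp <- structure(list(delta = delta,
                         groups = setNames(rep("nDR", n), colnames(delta))),
                    class = "response_matrix")
  got <- test_response_all(resp)
  rej <- mean(got$pvalue < 0.05)
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
  ord <- order(got$pvalue)
  expect_true(all(diff(got$qvalue[ord]) >= -1e-12))
  expect_true(all(got$qvalue <= 1))
})

test_that("differential response: antisymmetry, identical groups, pairing", {
  cfg <- tiny_config(seed = 20)
  panel <- simulate_reference_panel(cfg)
  st <- simulate_expression_study(cfg, panel)
  resp <- compute_response(st$expr)
  ab <- test_differential_response(resp, "PDR", "nDR")
  ba <- test_differential_response(resp, "nDR", "PDR")
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$pvalue, ba$pvalue, tolerance = 1e-12)
  # identical groups: duplicate the PDR columns under new labels
  resp0 <- resp
  pdr <- names(resp$groups)[resp$groups == "PDR"]
  resp0$delta <- cbind(resp$delta[, pdr], resp$delta[, pdr] +
                         matrix(rnorm(nrow(resp$delta) * length(pdr), 0, 1e-3),
                                nrow(resp$delta)))
  colnames(resp0$delta) <- c(pdr, paste0("c_", pdr))
  resp0$groups <- setNames(rep(c("PDR", "nDR"), each = length(pdr)),
                           colnames(resp0$delta))
  same <- test_differential_response(resp0, "PDR", "nDR")
  expect_lt(max(abs(same$log2fc)), 0.005)
  expect_gt(median(same$pvalue), 0.3)
  # paired mode runs and errors on bad pairing
  ndr <- names(resp$groups)[resp$groups == "nDR"]
  pairing <- setNames(ndr, pdr[seq_along(ndr)])
  pp <- test_differential_response(resp, "PDR", "nDR", pairing = pairing)
  expect_true(all(is.finite(pp$t)))
  expect_error(test_differential_response(resp, "PDR", "nDR",
                                          pairing = c(x1 = "nope")),
               class = "glucoMR_data_error")
  expect_error(test_differential_response(resp, "PDR", "XX"),
               class = "glucoMR_data_error")
})

test_that("true differential genes rank ahead of null genes", {
  wins <- sapply(1:20, function(s) {
    cfg <- tiny_config(seed = 300 + s, n_genes = 120L, n_response_genes = 40L,
                       n_diff_response_genes = 8L)
    panel <- simulate_reference_panel(cfg)
    st <- simulate_expression_study(cfg, panel)
    rd <- test_differential_response(compute_response(st$expr), "PDR", "nDR")
    rk <- rank(rd$pvalue)
    md <- median(rk[rd$gene_id %in% st$truth$diff_response_genes])
    mn <- median(rk[!rd$gene_id %in% st$truth$diff_response_genes])
    md < mn
  })
  expect_gte(mean(wins), 0.95)
})

test_that("label permutation yields uniform differential p-values", {
  set.seed(13)
  n <- 16
  delta <- matrix(rnorm(3000 * n), 3000, n,
                  dimnames = list(sprintf("g%04d", 1:3000),
                                  sprintf("i%02d", 1:n)))
  groups <- setNames(sample(rep(c("PDR", "nDR"), each = 8)), colnames(delta))
  resp <- structure(list(delta = delta, groups = groups),
                    class = "response_matrix")
  got <- test_differential_response(resp, "PDR", "nDR")
  expect_gt(suppressWarnings(ks.test(got$pvalue, "punif")$p.value), 0.01)
})

test_that("interindividual variance test: exchangeable vs structured", {
  # no individual-level response noise: within == between
  cfg0 <- tiny_config(seed = 21, n_genes = 300L, noise_sd_individual = 0,
                      response_effect = 0, diff_response_effect = 0,
                      n_response_genes = 0L, n_diff_response_genes = 0L)
  panel <- simulate_reference_panel(cfg0)
  st0 <- simulate_expression_study(cfg0, panel)
  iv0 <- interindividual_variance_test(st0$expr)
  expect_gt(iv0$p.value, 0.05)
  # single individual -> error
  lv <- layout_values(5, 1, 2, fill = 1)
  expr1 <- make_expr(lv$values, lv$grid$individual, lv$grid$replicate,
                     lv$grid$condition, rep("nDM", nrow(lv$grid)))
  expect_error(interindividual_variance_test(expr1),
               class = "glucoMR_data_error")
})

test_that("PCA covariate association finds planted group structure", {
  cfg <- tiny_config(seed = 22, n_genes = 400L, n_diff_response_genes = 40L,
                     n_response_genes = 100L, diff_response_effect = 0.8)
  panel <- simulate_reference_panel(cfg)
  st <- simulate_expression_study(cfg, panel)
  resp <- compute_response(st$expr)
  tab <- pca_covariate_association(resp, data.frame(
    group = unname(resp$groups),
    row.names = names(resp$groups)))
  expect_lt(min(tab$p[tab$PC == 1]), 0.01)
  # constant covariate skipped with warning
  expect_warning(
    empty <- pca_covariate_association(resp, data.frame(
      const = rep(1, ncol(resp$delta)), row.names = names(resp$groups))),
    "single level")
  expect_equal(nrow(empty), 0)
})
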