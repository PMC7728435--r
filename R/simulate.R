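# Synthetic-data module: genotype panel with AR(1) LD, paired SG/HG
# expression study, and eQTL/GWAS summary statistics under an
# expression-mediation disease model, with full ground truth.

#' Simulation configuration
#'
#' Encodes the generative "world" for the synthetic study: a matched
#' case/control lymphoblastoid glucose-challenge design (7 non-diabetic,
#' 7 diabetic without retinopathy, 8 with proliferative retinopathy; three
#' biological replicates per individual in each of standard-glucose and
#' high-glucose conditions), gene-level log2 expression with an
#' individual-specific glucose response and a group-by-glucose differential
#' effect for a subset of genes, plus eQTL and case-control GWAS summary
#' statistics in which disease liability is mediated through the expression
#' of designated genes.
#'
#' @param n_individuals_per_group named integer vector with counts for the
#'   `nDM`, `nDR` and `PDR` groups. Default `c(nDM = 7, nDR = 7, PDR = 8)`.
#' @param n_replicates biological replicates per individual and condition.
#' @param n_genes number of genes simulated. The default (2000) is a
#'   scaled-down transcriptome chosen for test speed; proportions of
#'   responsive genes are kept at study scale.
#' @param n_snps number of SNPs in the reference panel.
#' @param n_response_genes number of glucose-responsive genes. Default 22%
#'   of `n_genes`, matching the observed proportion of responding genes.
#' @param n_diff_response_genes number of genes with a group-by-glucose
#'   interaction (differential response). Must not exceed
#'   `n_response_genes`.
#' @param response_effect mean |log2 shift| under high glucose for
#'   responsive genes (sign randomized per gene).
#' @param diff_response_effect extra log2 response in the PDR group for
#'   differential-response genes. Default 0.27, the magnitude reported for
#'   the top differential-response locus.
#' @param noise_sd_gene SD of per-gene baseline log2 abundance around the
#'   grand mean.
#' @param noise_sd_individual SD of the per-(gene, individual) response
#'   deviation; this is what makes the response heritable across replicates
#'   within an individual.
#' @param noise_sd_replicate SD of the residual replicate-level noise.
#' @param maf_range two-element vector, minor allele frequencies drawn
#'   uniformly from this interval; must lie in (0, 0.5].
#' @param ld_rho AR(1) correlation of the latent Gaussian used to generate
#'   haplotypes; controls adjacent-SNP LD. In [0, 1).
#' @param eqtl_effect_sd SD of per-gene cis-eQTL effect sizes (log2
#'   expression per allele).
#' @param mediation_effect true causal effect of mediator-gene expression on
#'   disease liability, in liability SD per SD of expression (b_xy truth).
#' @param pleiotropy_effect direct (horizontal-pleiotropy) liability effect
#'   per allele of designated SNPs; default 0.
#' @param n_cases,n_controls case/control counts sampled for the GWAS.
#'   Defaults 973 and 1856, the meta-GWAS design counts.
#' @param prevalence population proportion above the liability threshold.
#' @param n_ref reference-panel individuals (LD estimation).
#' @param n_eqtl_samples cohort size for the eQTL summary statistics.
#' @param cis_window_snps number of panel SNPs on each side of a gene's
#'   causal eQTL that are tested (and reported) for that gene.
#' @param batch_effect optional per-replicate batch offset SD (log2 units);
#'   0 disables the batch term (replicates exchangeable).
#' @param gwas_model `"logistic"` fits per-SNP logistic regression on
#'   sampled case/control status; `"liability"` regresses the underlying
#'   continuous liability on dosage (linear), the scale on which the
#'   mediation identity b_zy = b_zx * b_xy is exact.
#' @param seed integer seed; all stages derive deterministic sub-streams.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals_per_group = c(nDM = 7L, nDR = 7L, PDR = 8L),
                       n_replicates = 3L,
                       n_genes = 2000L,
                       n_snps = 500L,
                       n_response_genes = round(0.22 * n_genes),
                       n_diff_response_genes = 20L,
                       response_effect = 0.25,
                       diff_response_effect = 0.27,
                       noise_sd_gene = 1,
                       noise_sd_individual = 0.1,
                       noise_sd_replicate = 0.25,
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0.7,
                       eqtl_effect_sd = 0.3,
                       mediation_effect = 0.15,
                       pleiotropy_effect = 0,
                       n_cases = 973L,
                       n_controls = 1856L,
                       prevalence = 0.34,
                       n_ref = 500L,
                       n_eqtl_samples = 500L,
                       cis_window_snps = 10L,
                       batch_effect = 0,
                       gwas_model = c("logistic", "liability"),
                       seed = 1L) {
  gwas_model <- match.arg(gwas_model)
  grp <- c("nDM", "nDR", "PDR")
  if (is.null(names(n_individuals_per_group))) {
    names(n_individuals_per_group) <- grp
  }
  if (!setequal(names(n_individuals_per_group), grp)) {
    stopf("glucoMR_config_error", "groups must be named nDM, nDR, PDR")
  }
  n_individuals_per_group <- vapply(n_individuals_per_group[grp], check_count,
                                    integer(1), name = "n_individuals_per_group")
  for (nm in c("n_replicates", "n_genes", "n_snps", "n_cases", "n_controls",
               "n_ref", "n_eqtl_samples")) {
    check_count(get(nm), nm)
  }
  n_response_genes <- check_count(n_response_genes, "n_response_genes", min = 0L)
  n_diff_response_genes <- check_count(n_diff_response_genes,
                                       "n_diff_response_genes", min = 0L)
  if (n_diff_response_genes > n_response_genes) {
    stopf("glucoMR_config_error",
          "n_diff_response_genes (%d) exceeds n_response_genes (%d)",
          n_diff_response_genes, n_response_genes)
  }
  if (n_response_genes > n_genes) {
    stopf("glucoMR_config_error", "n_response_genes exceeds n_genes")
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stopf("glucoMR_config_error", "maf_range must be within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) {
    stopf("glucoMR_config_error", "ld_rho must be in [0, 1)")
  }
  check_prob(prevalence, "prevalence")
  cfg <- list(
    n_individuals_per_group = n_individuals_per_group,
    n_replicates = as.integer(n_replicates),
    n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps),
    n_response_genes = as.integer(n_response_genes),
    n_diff_response_genes = as.integer(n_diff_response_genes),
    response_effect = response_effect,
    diff_response_effect = diff_response_effect,
    noise_sd_gene = noise_sd_gene,
    noise_sd_individual = noise_sd_individual,
    noise_sd_replicate = noise_sd_replicate,
    maf_range = maf_range,
    ld_rho = ld_rho,
    eqtl_effect_sd = eqtl_effect_sd,
    mediation_effect = mediation_effect,
    pleiotropy_effect = pleiotropy_effect,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    prevalence = prevalence,
    n_ref = as.integer(n_ref),
    n_eqtl_samples = as.integer(n_eqtl_samples),
    cis_window_snps = as.integer(cis_window_snps),
    batch_effect = batch_effect,
    gwas_model = gwas_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  individuals: %s (replicates: %d x {SG,HG})\n",
              paste(sprintf("%s=%d", names(x$n_individuals_per_group),
                            x$n_individuals_per_group), collapse = ", "),
              x$n_replicates))
  cat(sprintf("  genes: %d (%d responsive, %d differential)\n",
              x$n_genes, x$n_response_genes, x$n_diff_response_genes))
  cat(sprintf("  snps: %d, ld_rho = %.2f, mediation b_xy = %.3f\n",
              x$n_snps, x$ld_rho, x$mediation_effect))
  invisible(x)
}

# Draw an n x m dosage matrix: two haplotypes, each thresholding an AR(1)
# latent Gaussian (adjacent-SNP correlation rho) at qnorm(maf).
draw_dosages <- function(n, maf, rho) {
  m <- length(maf)
  thr <- stats::qnorm(maf)
  hap <- function() {
    z <- matrix(0, n, m)
    z[, 1] <- stats::rnorm(n)
    if (m > 1L) {
      s <- sqrt(1 - rho^2)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * stats::rnorm(n)
    }
    sweep(z, 2, thr, "<") + 0
  }
  hap() + hap()
}

#' Simulate a reference genotype panel with AR(1) linkage disequilibrium
#'
#' Dosages in {0,1,2} are produced by thresholding an AR(1)-correlated latent
#' Gaussian per haplotype at the quantile of each SNP's allele frequency and
#' summing two independent haplotypes. Adjacent-SNP LD is tuned by
#' `ld_rho`; `ld_rho = 0` gives independent SNPs.
#'
#' @param config a [sim_config()].
#' @param n_individuals panel size; defaults to `config$n_ref`.
#' @return object of class `genotype_panel`: list with `dosages`
#'   (individuals x SNPs), `snp_ids`, `allele_freqs` (generating
#'   frequencies), `ld_rho`.
#' @export
simulate_reference_panel <- function(config, n_individuals = config$n_ref) {
  stopifnot(inherits(config, "sim_config"))
  n <- check_count(n_individuals, "n_individuals")
  with_seed(stage_seed(config$seed, "panel"), {
    maf <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
    dos <- draw_dosages(n, maf, config$ld_rho)
    snp_ids <- sprintf("rs%06d", seq_len(config$n_snps))
    dimnames(dos) <- list(sprintf("ind_%04d", seq_len(n)), snp_ids)
    structure(list(dosages = dos, snp_ids = snp_ids, allele_freqs = maf,
                   ld_rho = config$ld_rho),
              class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs (ld_rho = %.2f)\n",
              nrow(x$dosages), ncol(x$dosages), x$ld_rho))
  invisible(x)
}

# Sample annotation for the study layout.
study_layout <- function(config) {
  groups <- rep(names(config$n_individuals_per_group),
                config$n_individuals_per_group)
  n_ind <- length(groups)
  ind <- sprintf("ind_%04d", seq_len(n_ind))
  samples <- expand.grid(replicate = seq_len(config$n_replicates),
                         condition = c("SG", "HG"),
                         individual = ind,
                         stringsAsFactors = FALSE)
  samples$group <- groups[match(samples$individual, ind)]
  samples$sample_id <- with(samples, paste(individual, condition, replicate,
                                           sep = "_"))
  samples[, c("sample_id", "individual", "replicate", "condition", "group")]
}

#' Simulate a paired SG/HG expression study with ground truth
#'
#' Generates replicate-level log2 expression following
#' `baseline_g + u_i + beta_eqtl * dosage + (response_g + gamma_gi) * HG +
#'  diff_g * HG * PDR + eps`, where `gamma_gi` is the per-individual response
#' deviation (SD `noise_sd_individual`) and `eps` is replicate noise
#' (SD `noise_sd_replicate`). `response_g` is nonzero only for response
#' genes, `diff_g` only for differential-response genes (a subset).
#'
#' @param config a [sim_config()].
#' @param panel a [simulate_reference_panel()] result with at least as many
#'   individuals as the study requires.
#' @return list with `expr` (an `expression_matrix`) and `truth`
#'   (a `truth_table`).
#' @export
simulate_expression_study <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  n_ind <- sum(config$n_individuals_per_group)
  if (nrow(panel$dosages) < n_ind) {
    stopf("glucoMR_config_error",
          "panel has %d individuals; study needs %d", nrow(panel$dosages), n_ind)
  }
  samples <- study_layout(config)
  gene_ids <- sprintf("gene_%05d", seq_len(config$n_genes))
  with_seed(stage_seed(config$seed, "expression"), {
    response_genes <- sort(sample(gene_ids, config$n_response_genes))
    diff_genes <- sort(sample(response_genes, config$n_diff_response_genes))
    # per-gene cis-eQTL assignment: distinct SNPs while available
    snp_assign <- if (config$n_snps >= config$n_genes) {
      sample(panel$snp_ids, config$n_genes)
    } else {
      sample(rep_len(panel$snp_ids, config$n_genes))
    }
    eqtl_beta <- stats::rnorm(config$n_genes, 0, config$eqtl_effect_sd)
    baseline <- stats::rnorm(config$n_genes, 8, config$noise_sd_gene)
    resp_sign <- sample(c(-1, 1), config$n_genes, replace = TRUE)
    response <- ifelse(gene_ids %in% response_genes,
                       resp_sign * config$response_effect, 0)
    diff_eff <- ifelse(gene_ids %in% diff_genes, config$diff_response_effect, 0)

    dos_study <- panel$dosages[seq_len(n_ind), , drop = FALSE]
    ind_ids <- unique(samples$individual)
    u_i <- stats::rnorm(n_ind, 0, config$noise_sd_individual)
    names(u_i) <- ind_ids
    gamma <- matrix(stats::rnorm(config$n_genes * n_ind, 0,
                                 config$noise_sd_individual),
                    config$n_genes, n_ind, dimnames = list(gene_ids, ind_ids))
    dos_g <- dos_study[match(samples$individual, rownames(dos_study)),
                       snp_assign, drop = FALSE]            # sample x gene

    is_hg <- as.numeric(samples$condition == "HG")
    is_pdr <- as.numeric(samples$group == "PDR")
    idx_ind <- match(samples$individual, ind_ids)

    vals <- matrix(0, config$n_genes, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
    # gene x sample mean surface, built by columns
    for (s in seq_len(nrow(samples))) {
      vals[, s] <- baseline + u_i[idx_ind[s]] + eqtl_beta * dos_g[s, ] +
        (response + gamma[, idx_ind[s]]) * is_hg[s] +
        diff_eff * is_hg[s] * is_pdr[s]
    }
    if (config$batch_effect > 0) {
      batch_off <- stats::rnorm(config$n_replicates, 0, config$batch_effect)
      vals <- vals + rep(batch_off[samples$replicate], each = config$n_genes)
    }
    vals <- vals + matrix(stats::rnorm(length(vals), 0, config$noise_sd_replicate),
                          nrow(vals), ncol(vals))

    expr <- expression_matrix(vals, samples)
    # when a direct (pleiotropic) path is requested, plant it on the SNP
    # adjacent to each mediator gene's causal eQTL so it sits inside the locus
    pleio <- character(0)
    if (config$pleiotropy_effect != 0 && length(diff_genes) > 0) {
      causal <- snp_assign[match(diff_genes, gene_ids)]
      idx <- match(causal, panel$snp_ids)
      pleio <- panel$snp_ids[pmin(idx + 1L, length(panel$snp_ids))]
    }
    truth <- structure(list(
      response_genes = response_genes,
      diff_response_genes = diff_genes,
      eqtl_map = data.frame(gene_id = gene_ids, snp_id = snp_assign,
                            beta = eqtl_beta, stringsAsFactors = FALSE),
      true_b_xy = config$mediation_effect,
      pleiotropic_snps = pleio
    ), class = "truth_table")
    list(expr = expr, truth = truth)
  })
}

# steady-state (single-measure) expression for a genotype cohort:
# baseline + beta * dosage + N(0, sd_ind^2 + sd_rep^2)
steady_state_expression <- function(config, truth, dosages) {
  sd_e <- sqrt(config$noise_sd_individual^2 + config$noise_sd_replicate^2)
  n <- nrow(dosages)
  g <- truth$eqtl_map
  x <- dosages[, g$snp_id, drop = FALSE] *
    rep(g$beta, each = n)
  x + matrix(stats::rnorm(n * nrow(g), 0, sd_e), n, nrow(g),
             dimnames = list(rownames(dosages), g$gene_id))
}

# vectorized per-column simple regression of y on each column of X
col_regress <- function(X, y) {
  n <- length(y)
  xm <- colMeans(X)
  ym <- mean(y)
  sxx <- colSums(X^2) - n * xm^2
  sxy <- colSums(X * y) - n * xm * ym
  beta <- sxy / sxx
  res_ss <- sum((y - ym)^2) - beta * sxy
  se <- sqrt(pmax(res_ss, 0) / ((n - 2) * sxx))
  tt <- beta / se
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  data.frame(beta = beta, se = se, pvalue = p)
}

#' Simulate eQTL and GWAS summary statistics under expression mediation
#'
#' Draws an eQTL cohort and a GWAS population with the same allele
#' frequencies and LD process as `panel`. eQTL rows are per-SNP simple
#' regressions of standardized steady-state expression on dosage over each
#' gene's cis window. Disease liability is
#' `b_xy * (genetic expression component / total expression SD)` summed over
#' mediator genes (the differential-response genes), plus any direct
#' (pleiotropic) allele effects and standard-normal noise; cases and
#' controls are sampled by liability threshold and per-SNP GWAS effects are
#' estimated by logistic regression (or linear-on-liability when
#' `config$gwas_model == "liability"`).
#'
#' @param config a [sim_config()].
#' @param panel a [simulate_reference_panel()] result (supplies allele
#'   frequencies and the LD process for the fresh cohorts).
#' @param truth a `truth_table` from [simulate_expression_study()].
#' @return list with `eqtl` (an `EqtlTable` data frame: gene_id, snp_id,
#'   tissue, beta, se, pvalue, fdr), `gwas` (snp_id, chrom, pos_1based,
#'   effect_allele, other_allele, beta, se, pvalue).
#' @export
simulate_summary_statistics <- function(config, panel, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"),
            inherits(truth, "truth_table"))
  if (nrow(truth$eqtl_map) == 0L) {
    stopf("glucoMR_config_error", "truth$eqtl_map is empty")
  }
  with_seed(stage_seed(config$seed, "sumstats"), {
    m <- length(panel$snp_ids)
    ## ---- eQTL cohort ----
    dos_e <- draw_dosages(config$n_eqtl_samples, panel$allele_freqs,
                          config$ld_rho)
    colnames(dos_e) <- panel$snp_ids
    expr_e <- steady_state_expression(config, truth, dos_e)
    causal_idx <- match(truth$eqtl_map$snp_id, panel$snp_ids)
    w <- config$cis_window_snps
    eqtl_rows <- vector("list", nrow(truth$eqtl_map))
    for (g in seq_len(nrow(truth$eqtl_map))) {
      lo <- max(1L, causal_idx[g] - w)
      hi <- min(m, causal_idx[g] + w)
      cis <- lo:hi
      fit <- col_regress(dos_e[, cis, drop = FALSE],
                         as.numeric(scale(expr_e[, g])))
      eqtl_rows[[g]] <- data.frame(
        gene_id = truth$eqtl_map$gene_id[g],
        snp_id = panel$snp_ids[cis],
        tissue = "simulated",
        beta = fit$beta, se = fit$se, pvalue = fit$pvalue,
        stringsAsFactors = FALSE)
    }
    eqtl <- do.call(rbind, eqtl_rows)
    eqtl$fdr <- bh_adjust(eqtl$pvalue)
    rownames(eqtl) <- NULL

    ## ---- GWAS cohort ----
    n_pop <- ceiling(1.5 * (config$n_cases + config$n_controls))
    dos_p <- draw_dosages(n_pop, panel$allele_freqs, config$ld_rho)
    colnames(dos_p) <- panel$snp_ids
    mediators <- truth$eqtl_map[truth$eqtl_map$gene_id %in%
                                  truth$diff_response_genes, , drop = FALSE]
    sd_x <- sqrt(config$noise_sd_individual^2 + config$noise_sd_replicate^2)
    genetic <- rep(0, n_pop)
    if (nrow(mediators) > 0 && truth$true_b_xy != 0) {
      for (g in seq_len(nrow(mediators))) {
        d <- dos_p[, mediators$snp_id[g]]
        gc <- mediators$beta[g] * (d - mean(d))   # centered: keeps the
        tot_sd <- sqrt(mediators$beta[g]^2 *      # liability mean at zero
                         stats::var(d) + sd_x^2)  # without changing slopes
        genetic <- genetic + truth$true_b_xy * gc / tot_sd
      }
    }
    if (length(truth$pleiotropic_snps) > 0 && config$pleiotropy_effect != 0) {
      for (s in truth$pleiotropic_snps) {
        d <- dos_p[, s]
        genetic <- genetic + config$pleiotropy_effect * (d - mean(d))
      }
    }
    liability <- genetic + stats::rnorm(n_pop)
    thr <- stats::qnorm(1 - config$prevalence)
    case_pool <- which(liability > thr)
    ctrl_pool <- which(liability <= thr)
    if (length(case_pool) < config$n_cases ||
        length(ctrl_pool) < config$n_controls) {
      stopf("glucoMR_simulation_error",
            "liability sampling yielded %d cases and %d controls (need %d / %d); raise prevalence or lower the requested counts",
            length(case_pool), length(ctrl_pool),
            config$n_cases, config$n_controls)
    }
    keep <- c(sample(case_pool, config$n_cases),
              sample(ctrl_pool, config$n_controls))
    y <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
    D <- dos_p[keep, , drop = FALSE]

    if (config$gwas_model == "liability") {
      fit <- col_regress(D, liability[keep])
    } else {
      fit <- data.frame(beta = numeric(m), se = numeric(m), pvalue = numeric(m))
      for (j in seq_len(m)) {
        gl <- stats::glm.fit(cbind(1, D[, j]), y,
                             family = stats::binomial())
        cf <- gl$coefficients[2]
        # Wald se from the Fisher information at convergence
        XtWX <- crossprod(cbind(1, D[, j]) * sqrt(gl$weights))
        se <- sqrt(solve(XtWX)[2, 2])
        fit$beta[j] <- cf
        fit$se[j] <- se
        fit$pvalue[j] <- 2 * stats::pnorm(-abs(cf / se))
      }
    }
    gwas <- data.frame(
      snp_id = panel$snp_ids,
      chrom = "1",
      pos_1based = seq_len(m) * 1000L,
      effect_allele = "A",
      other_allele = "G",
      beta = fit$beta, se = fit$se, pvalue = pmin(pmax(fit$pvalue, 1e-300), 1),
      stringsAsFactors = FALSE)
    list(eqtl = eqtl, gwas = gwas)
  })
}
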