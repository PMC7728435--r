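# End-to-end orchestration: simulate (or load) -> response tests -> GSEA ->
# eSNP/GWAS enrichment -> Mendelian randomization, with one seed, plain
# TSV/JSON stage outputs and a machine-readable top-level report.

#' Pipeline run configuration
#'
#' Either a simulation block (a [sim_config()] or its argument list) or
#' paths to pre-built inputs (expression/eQTL/GWAS/panel TSVs, GMT file).
#'
#' @param simulation a [sim_config()], an argument list for it, or `NULL`
#'   when file inputs are given.
#' @param expression_tsv,eqtl_tsv,gwas_tsv,panel_tsv,gmt input file paths
#'   (ignored when `simulation` is supplied).
#' @param response_p_cut p-value cutoff defining top differential-response
#'   genes (default 0.01).
#' @param eqtl_fdr_max eQTL significance threshold (default 0.05).
#' @param gwas_alpha nominal GWAS threshold (default 0.05).
#' @param r2_prune,r2_proxy LD thresholds for pruning and proxy search.
#' @param n_permutations random-eGene permutation draws (default 1000 for
#'   interactive runs; raise to 10000 for final reports).
#' @param gsea_n_perm gene-set permutations (default 1000).
#' @param seed top-level seed.
#' @param out_dir output directory (created if missing); `NULL` disables
#'   file output.
#' @return object of class `run_config`.
#' @export
run_config <- function(simulation = list(),
                       expression_tsv = NULL, eqtl_tsv = NULL,
                       gwas_tsv = NULL, panel_tsv = NULL, gmt = NULL,
                       response_p_cut = 0.01, eqtl_fdr_max = 0.05,
                       gwas_alpha = 0.05, r2_prune = 0.2, r2_proxy = 0.8,
                       n_permutations = 1000L, gsea_n_perm = 1000L,
                       seed = 1L, out_dir = NULL) {
  check_prob(response_p_cut, "response_p_cut")
  check_prob(eqtl_fdr_max, "eqtl_fdr_max")
  check_prob(gwas_alpha, "gwas_alpha")
  check_prob(r2_prune, "r2_prune")
  check_prob(r2_proxy, "r2_proxy")
  sim <- NULL
  if (!is.null(simulation)) {
    sim <- if (inherits(simulation, "sim_config")) {
      simulation
    } else {
      simulation$seed <- NULL   # the run seed governs
      do.call(sim_config, c(simulation, list(seed = seed)))
    }
  }
  if (is.null(sim) && (is.null(expression_tsv) || is.null(eqtl_tsv) ||
                       is.null(gwas_tsv) || is.null(panel_tsv))) {
    stopf("glucoMR_config_error",
          "either a simulation block or all four input paths are required")
  }
  structure(list(simulation = sim, expression_tsv = expression_tsv,
                 eqtl_tsv = eqtl_tsv, gwas_tsv = gwas_tsv,
                 panel_tsv = panel_tsv, gmt = gmt,
                 response_p_cut = response_p_cut, eqtl_fdr_max = eqtl_fdr_max,
                 gwas_alpha = gwas_alpha, r2_prune = r2_prune,
                 r2_proxy = r2_proxy,
                 n_permutations = as.integer(n_permutations),
                 gsea_n_perm = as.integer(gsea_n_perm),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, glucoMR_error = function(e) {
    stopf("glucoMR_stage_error",
          "stage '%s' failed: %s (check the stage inputs and thresholds)",
          name, conditionMessage(e))
  })
}

# auto-generated gene sets for simulation mode: random sets plus one set
# planted on the true response genes
default_gene_sets <- function(truth, gene_ids, n_sets = 20L, seed = 1L) {
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i)
      sample(gene_ids, sample(20:100, 1)))
    names(sets) <- sprintf("random_set_%02d", seq_len(n_sets))
    sets$planted_response <- sample(truth$response_genes,
                                    min(50, length(truth$response_genes)))
    sets
  })
}

#' Run the full pipeline
#'
#' Executes simulate/load, response testing (overall and differential),
#' pi1 summaries, preranked GSEA, eSNP-GWAS enrichment with the
#' random-eGene permutation null, and the SMR/HEIDI/multi-SNP MR block for
#' the top mediator locus. Stage outputs are written as TSV/JSON under
#' `config$out_dir` when set; a top-level report list is returned
#' (and written as `report.json`).
#'
#' @param config a [run_config()].
#' @return the report, invisibly a list with per-stage summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  save_tsv <- function(x, f) if (!is.null(out)) write_table_tsv(x, file.path(out, f))

  ## stage 1: data
  truth <- NULL
  panel <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    panel <- stage("simulate", simulate_reference_panel(sim))
    st <- stage("simulate", simulate_expression_study(sim, panel))
    expr <- st$expr
    truth <- st$truth
    ss <- stage("simulate", simulate_summary_statistics(sim, panel, truth))
    eqtl <- ss$eqtl
    gwas <- ss$gwas
    if (!is.null(out)) {
      write_expression_tsv(expr, file.path(out, "expression.tsv"))
      save_tsv(eqtl, "eqtl.tsv")
      save_tsv(gwas, "gwas.tsv")
      write_panel_tsv(panel, file.path(out, "panel.tsv"))
      write_truth_json(truth, file.path(out, "truth.json"))
    }
  } else {
    expr <- stage("load", read_expression_tsv(config$expression_tsv))
    eqtl <- stage("load", read_eqtl_tsv(config$eqtl_tsv))
    gwas <- stage("load", read_gwas_tsv(config$gwas_tsv))
    panel <- stage("load", read_panel_tsv(config$panel_tsv))
  }

  ## stage 2: response tests
  resp <- stage("respond", compute_response(expr))
  res_all <- stage("respond", test_response_all(resp))
  pi1_all <- estimate_pi0(res_all$pvalue)
  res_diff <- stage("respond", test_differential_response(resp, "PDR", "nDR"))
  top_genes <- res_diff$gene_id[res_diff$pvalue < config$response_p_cut]
  save_tsv(res_all, "response_all.tsv")
  save_tsv(res_diff, "response_diff.tsv")
  log_msg("info", "response: pi1(all) = %.3f; %d differential genes at p < %g",
          pi1_all$pi1, length(top_genes), config$response_p_cut)

  ## stage 3: GSEA
  gsea_res <- NULL
  gene_sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
               else if (!is.null(truth))
                 default_gene_sets(truth, res_all$gene_id,
                                   seed = stage_seed(config$seed, "gsea"))
  if (!is.null(gene_sets)) {
    ranked <- rank_genes(res_all)
    gsea_res <- stage("gsea", gsea_preranked(
      ranked, gene_sets, n_perm = config$gsea_n_perm,
      seed = stage_seed(config$seed, "gsea")))
    save_tsv(gsea_res, "gsea.tsv")
  }

  ## stage 4: eSNP/GWAS enrichment
  esnps <- stage("enrich", esnps_for_genes(eqtl, top_genes,
                                           config$eqtl_fdr_max))
  enr <- NULL
  perm <- NULL
  if (length(esnps) > 0) {
    enr <- stage("enrich", gwas_enrichment(esnps, gwas, config$gwas_alpha))
    perm <- stage("enrich", permutation_enrichment(
      enr$proportion_small_p, k_genes = length(top_genes), eqtl = eqtl,
      gwas = gwas, B = config$n_permutations, alpha = config$gwas_alpha,
      fdr_max = config$eqtl_fdr_max,
      seed = stage_seed(config$seed, "permutation")))
    if (!is.null(out)) save_tsv(enr$qq, "qq_points.tsv")
  }

  ## stage 5: Mendelian randomization at the top mediator locus
  mr <- NULL
  if (length(esnps) > 0 && !is.null(panel)) {
    sig <- eqtl[eqtl$fdr <= config$eqtl_fdr_max & eqtl$gene_id %in% top_genes, ]
    if (nrow(sig) > 0) {
      mr_gene <- names(sort(table(sig$gene_id), decreasing = TRUE))[1]
      rows_e <- eqtl[eqtl$gene_id == mr_gene, ]
      inst <- stage("mr", harmonize(rows_e, gwas))
      inst <- inst[inst$snp_id %in% colnames(panel$dosages), , drop = FALSE]
      if (nrow(inst) >= 1) {
        ld <- stage("mr", compute_ld(panel, inst$snp_id))
        inst <- inst[inst$snp_id %in% rownames(ld), , drop = FALSE]
        top_i <- inst[which.min(inst$p_zx), , drop = FALSE]
        smr <- stage("mr", smr_test(top_i))
        heidi <- stage("mr", heidi_test(inst, ld))
        pruned <- stage("mr", prune_ld(inst, ld, config$r2_prune))
        multi <- stage("mr", multi_snp_smr(pruned, ld))
        mr <- list(gene = mr_gene, b_xy = smr$b_xy, se_xy = smr$se_xy,
                   p_smr = smr$p_smr, top_snp = smr$snp_id,
                   p_heidi = heidi$p, heidi_n = heidi$n_used,
                   p_multi = multi$p, n_instruments = multi$n_instruments,
                   pruned_ids = pruned$snp_id)
        save_tsv(as.data.frame(inst), "mr_instruments.tsv")
      }
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("glucoMR")),
    seed = config$seed,
    thresholds = config[c("response_p_cut", "eqtl_fdr_max", "gwas_alpha",
                          "r2_prune", "r2_proxy")],
    n_genes_analyzed = nrow(resp$delta),
    n_individuals = ncol(resp$delta),
    pi1_response_all = pi1_all$pi1,
    n_top_differential_genes = length(top_genes),
    top_differential_genes = top_genes,
    n_esnps = length(esnps),
    gwas_enrichment = if (!is.null(enr)) list(
      proportion_small_p = enr$proportion_small_p,
      bh_min_q = enr$bh_min_q, n_bh_hits = enr$n_bh_hits,
      bonferroni_threshold = enr$bonferroni_threshold,
      lambda_gc = enr$lambda_gc),
    permutation_p = if (!is.null(perm)) perm$p,
    gsea_top = if (!is.null(gsea_res))
      utils::head(gsea_res[order(gsea_res$pvalue), ], 5),
    mr = mr
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
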