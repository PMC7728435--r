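# glucoMR

An R package for asking whether **interindividual differences in the
transcriptional response to glucose are genetically regulated and causally
linked to disease** — the analytical chain used to connect a
lymphoblastoid-cell-line (LCL) glucose-challenge experiment to diabetic
retinopathy genetics, reimplemented as a tested, reusable pipeline that
runs entirely offline on synthetic data with known ground truth.

## Who it is for

Statistical geneticists and computational biologists who want the pieces of
an expression-to-disease integrative analysis — moderated response testing,
preranked GSEA, Storey π1, eQTL–GWAS enrichment with a permutation null, and
summary-data Mendelian randomization (SMR/HEIDI/multi-SNP) — as composable,
unit-tested functions, plus a generator that simulates the whole study
design (genotypes with LD, paired-condition expression, eQTL and
case-control GWAS summary statistics under an expression-mediation disease
model).

## The model

**Glucose response.** For individual *i* and gene *k*, the response is
Δ<sub>i,k</sub> = HG<sub>i,k</sub> − SG<sub>i,k</sub> (high- minus
standard-glucose log2 expression, replicates collapsed to means). Gene-wise
variances are shrunk toward a common value via the scaled-inverse-χ²
empirical-Bayes model: s̃² = (d₀s₀² + d·s²)/(d₀ + d), with (d₀, s₀²)
estimated by moment matching on log s², giving moderated t-statistics with
d₀ + d df. The *overall* response tests mean(Δ) ≠ 0 across individuals; the
*differential* response contrasts Δ between outcome groups (e.g.
proliferative retinopathy vs no retinopathy).

**Enrichment.** Genes are ranked by sign(FC)·(−log₁₀ p) for preranked GSEA
with a weighted running-sum score and a gene-set permutation null. Storey's
π1 = 1 − π̂0 summarizes the fraction of tests under the alternative. eSNPs
of the top differential genes are tested for small GWAS p-values
(proportion < α, BH within the set, Bonferroni threshold, genomic-control
λ<sub>GC</sub>), against a null of 10,000 random same-size eGene sets.

**Mendelian randomization.** With b<sub>zx</sub> (expression per allele)
and b<sub>zy</sub> (disease per allele), SMR estimates
b<sub>xy</sub> = b<sub>zy</sub>/b<sub>zx</sub> with
T = z²<sub>zx</sub>z²<sub>zy</sub>/(z²<sub>zx</sub> + z²<sub>zy</sub>) ~ χ²₁.
HEIDI tests heterogeneity of per-SNP b<sub>xy</sub> across LD-linked
instruments (rejection ⇒ horizontal pleiotropy/linkage); multi-SNP SMR sums
the per-instrument statistics over an LD-pruned (r² < 0.2) set with a
weighted-χ² null. LD comes from a reference genotype panel, with greedy
pruning and proxy search (r² > 0.8).

## Worked example

Simulate the default study world — 22 individuals (7 non-diabetic, 7
diabetic without retinopathy, 8 with proliferative retinopathy), 3
replicates × {SG, HG}, 2000 genes of which 22% respond to glucose and 20
respond differentially by 0.27 log2 units, one cis-eQTL per gene, and a
973-case/1856-control GWAS in which disease liability is mediated through
the differential-response genes with b<sub>xy</sub> = 0.15:

```r
library(glucoMR)
cfg   <- sim_config(seed = 1)
panel <- simulate_reference_panel(cfg)
st    <- simulate_expression_study(cfg, panel)
resp  <- compute_response(st$expr)

estimate_pi0(test_response_all(resp)$pvalue)
#> <pi1_estimate> pi1 = 0.229 (pi0 = 0.771, method = smoother, m = 2000)

res_diff <- test_differential_response(resp, "PDR", "nDR")
top <- res_diff$gene_id[res_diff$pvalue < 0.01]   # 37 genes; 12 of the 20 planted

ss    <- simulate_summary_statistics(cfg, panel, st$truth)
esnps <- esnps_for_genes(ss$eqtl, top)
gwas_enrichment(esnps, ss$gwas)
#> <enrichment_summary> 147 eSNPs; prop(p<alpha) = 0.2041; lambda_GC = 1.806
#>   BH hits (q<0.05): 13; Bonferroni threshold 3.40e-04 (7 hits)

gene <- st$truth$diff_response_genes[1]
inst <- harmonize(ss$eqtl[ss$eqtl$gene_id == gene, ], ss$gwas)
ld   <- compute_ld(panel, inst$snp_id)
smr_test(inst[which.min(inst$p_zx), ])
#> <smr_result> b_xy = 0.2676 (se 0.0731), T = 13.418, p = 0.000249 [rs000442]
heidi_test(inst, ld)$p                      # 0.282  -> no pleiotropy detected
multi_snp_smr(prune_ld(inst, ld, 0.2), ld)  # 13 instruments, p = 0.19
```

Reading the output: 22.9% of genes respond to glucose (π1, matching the
planted 22%); the eSNPs of the differential-response genes are four-fold
enriched for small GWAS p-values (20.4% < 0.05 vs the 5% null expectation;
λ<sub>GC</sub> ≫ 1 here reflects true planted signal, not confounding); the
mediator locus shows a significant SMR effect with a non-significant HEIDI
p, the signature of mediation rather than pleiotropy. The SMR b_xy is on
the log-odds scale here (logistic GWAS default) and is therefore larger
than the liability-scale truth of 0.15; `sim_config(gwas_model =
"liability")` makes the identity exact.

One call runs everything (simulate → respond → GSEA → enrichment → MR) and
writes TSV/JSON stage outputs plus a machine-readable report:

```r
report <- run_pipeline(run_config(simulation = sim_config(seed = 1),
                                  out_dir = "run1"))
```

A command-line wrapper with subcommands `simulate | respond | gsea |
enrich | mr | run-all` lives at `inst/cli/glucomr.R`:

```sh
Rscript inst/cli/glucomr.R run-all --seed 1 --out run1
```

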