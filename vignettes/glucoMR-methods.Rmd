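---
title: "glucoMR: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glucoMR: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

glucoMR implements an integrative inference chain that links
interindividual transcriptional response to glucose with genetic
association: moderated response and differential-response testing,
preranked gene-set enrichment, Storey π1 summaries, eSNP–GWAS enrichment
with a random-eGene permutation null, and summary-data Mendelian
randomization (SMR, HEIDI, multi-SNP SMR). This vignette records the
statistical models, the assumptions behind the synthetic-data generator,
and the numerical and design choices a maintainer would want to know.
Every number quoted here is computed by the package's test suite or the
examples in the README; nothing is asserted that the code does not measure.

## 1. The response model

The unit of analysis is the per-individual response to glucose,
Δ~i,k~ = HG~i,k~ − SG~i,k~ in log2 units, after collapsing biological
replicates to per-(individual, condition) means. With exchangeable
replicates the per-individual mean is the sufficient statistic for Δ, so a
consensus-correlation mixed model over replicates is deliberately not
fitted; the replicate structure instead feeds the inter- vs
intra-individual variability test (below). Individuals missing one
condition are dropped with a log entry.

Gene-wise variances are moderated with the standard empirical-Bayes
scaled-inverse-χ² model. Writing s² for a gene's sample variance on d
residual df, the posterior variance is s̃² = (d₀s₀² + d·s²)/(d₀ + d) and
the moderated t has d₀ + d df. The prior (d₀, s₀²) is fitted by moment
matching on e = log s²: solve trigamma(d₀/2) = var(e) − trigamma(d/2) by
Newton iteration (tolerance 1e-8), then recover s₀² from mean(e) with the
digamma corrections. Two boundary conventions matter:

* if var(e) ≤ trigamma(d/2) there is no excess spread and d₀ = ∞ (full
  shrinkage); s₀² is then the geometric mean exp(mean(e)). The
  digamma-corrected formula would return 1.11 × the common value when all
  variances are identical, which is neither the intuitive answer nor what
  limma does, so the geometric mean is used on this branch only.
* d₀ = 0 recovers the classical t exactly (tested to 1e-10 over 10,000
  genes), and d₀ = ∞ gives t = mean(Δ)·√n/s₀ exactly.

The finite-d₀ branch agrees with `limma::squeezeVar` within 5% on a
simulated F-distributed variance set; limma is used only as a test oracle,
never in the inference path.

The differential-response test contrasts Δ between groups (default PDR vs
nDR) as a two-sample moderated t with pooled variance; a paired mode
(one-sample moderated t on matched differences) is provided because the
source design matched cases to controls. The reported effect is the
difference of mean log2 responses, group_a − group_b.

**Inter- vs intra-individual variability.** The test pairs HG replicate r
with SG replicate r within each individual to form replicate-level response
profiles, computes all pairwise Pearson correlations between profiles, and
compares within-individual to between-individual correlations with a
one-sided Wilcoxon rank-sum test. The construction is a stated stand-in:
the source analysis did not specify its test, and any statistic that
detects individual-level response variance components would do. Under the
generator with no individual-level response noise the p-value is uniform;
with individual noise ≫ replicate noise it rejects essentially always
(tested).

**PCA QC.** Principal components of the gene × individual Δ matrix are
tested against covariates by linear model (numeric) or one-way ANOVA
(categorical), first 5 PCs by default; single-level covariates are skipped
with a warning.

## 2. Preranked GSEA

Genes are ranked by sign(effect) × (−log₁₀ p); zero p-values are clamped to
the smallest positive double, duplicate ids keep the entry with the largest
|score|, and score ties break by gene id so the ranking is deterministic.
The enrichment score is the signed maximum deviation of the Subramanian
running sum (hit increments |score|^w normalized over set members, miss
decrements 1/(N − N_hit)); the default weight w = 1 is the classic
"weighted" statistic — the source method section does not state its
exponent, so this default is configurable. Zero-score genes contribute to
the miss side only. Set-size bounds default to [15, 500] after intersection
with the ranked list.

Significance uses a **gene-set permutation** null (random same-size sets of
ranked genes), as stated by the source method, not phenotype permutation.
NES divides ES by the mean |null ES| of the same sign; the nominal p is the
add-one-smoothed same-sign tail. Note a consequence: the attainable p floor
is 1/(1 + #same-sign nulls) ≈ 2/n_perm, not 1/(1 + n_perm). FDR follows the
sign-stratified NES procedure (pooled normalized null NES tail over
observed NES tail, clipped to [0, 1]).

## 3. Storey π1

π̂0(λ) = #{p > λ}/(m(1 − λ)) over λ = 0.05, …, 0.95. The smoother method
fits a cubic smoothing spline (3 effective df) to π̂0(λ) and evaluates at
λ = 0.95 — the standard qvalue construction. An unweighted cubic
*polynomial* was tried first and rejected: the last grid point has binomial
standard error ≈ 0.04 at m = 10,000, the polynomial endpoint chases that
noise, and recovery of a planted 22% alternative fraction missed its ±0.05
tolerance (error 0.058 vs 0.042 for the spline). For small inputs
(m < 500, e.g. a few hundred instrument SNPs) the default switches to the
fixed-λ estimator at λ = 0.5, whose closed form 1 − 2·#{p > 0.5}/m is exact
and far less variable; the smoother remains forcible.

## 4. eSNP–GWAS enrichment

eSNPs of a gene list are the unique SNPs with eQTL FDR ≤ 0.05 for any
listed gene in any tissue; eGenes are genes with at least one such SNP.
Enrichment summaries: the proportion of GWAS p < α among the eSNPs, BH FDR
computed *within* the eSNP set (the source's convention, motivated by LD
among eSNPs), the Bonferroni threshold α/n, genomic-control
λ_GC = median(χ²₁ quantiles of 1 − p)/0.45494, and QQ points. SNP matching
is exact case-normalized id match; no positional liftover.

The permutation null draws B random same-size eGene sets from the eGene
universe (all eGenes, matching the source's "random samples of eGenes"),
collects their eSNPs, and recomputes the statistic. Both reported variants
are implemented — proportion of GWAS p < 0.05 (default) and BH-hit count —
because the source text is ambiguous about which generated its printed
figure; results label which was used. Empirical p is add-one smoothed,
bounded below by 1/(1 + B). Calibration under the no-mediation generator is
an acceptance criterion (KS uniformity over 200 repetitions).

## 5. Summary-data Mendelian randomization

Instruments are harmonized by joining eQTL and GWAS rows on SNP id,
flipping the GWAS effect where effect/other alleles are swapped and
dropping strand-ambiguous (A/T, C/G) SNPs — frequency-based strand
inference is deliberately not attempted. LD is the Pearson correlation of
reference-panel dosages with a 1e-6 ridge folded in (unit diagonal, PSD).
Pruning is greedy in order of increasing exposure p-value with ties broken
by SNP id, accepting a SNP iff r² < 0.2 against all accepted ones; an
optional exhaustive verification re-checks every retained pair. Proxy
search returns SNPs with r² > 0.8 to a query, sorted.

SMR: b_xy = b_zy/b_zx, T = z²_zx·z²_zy/(z²_zx + z²_zy) against χ²₁,
se_xy = |b_xy|/√T. T is stochastically *below* χ²₁ unless the instrument is
strong (deflation ~ z²_zy/z²_zx), which is why both the type-I acceptance
test and sensible practice filter instruments (p_zx < 5e-8 by convention).

HEIDI: the top SNP is the smallest exposure p; instruments require
p_zx < 1.6e-3, r² to the top SNP within [0.05, 0.9], capped at the 20
smallest exposure p-values — the published SMR tool's defaults, adopted
because the source states only the multi-SNP pruning threshold; all are
configurable. d_i = b_xy,i − b_xy,top is standardized by first-order
(delta-method) error propagation in which b_zx and b_zy correlate across
SNPs through LD r but are independent of each other (non-overlapping
samples). T = Σ z²_d is referred to the weighted-χ² null with weights from
the eigenvalues of the correlation matrix of the d's. Fewer than 3 usable
instruments yields a "not testable" result object, not an error.

Multi-SNP SMR sums per-instrument T over the pruned set; the null is the
weighted χ² with weights from the eigenvalues of the squared-LD (r²)
matrix, which reduces exactly to χ²_m for independent instruments (tested
against Monte-Carlo). All weighted-χ² tails use Satterthwaite moment
matching (scaled χ² with matched mean and variance) — adequate at α ≥
0.001 and dependency-free; extreme tail p-values (≪ 1e-4) from this
approximation should not be over-interpreted.

## 6. The synthetic world

The generator's defaults are the study design, not tunable dials:
22 individuals (7 nDM, 7 nDR, 8 PDR), 3 replicates × {SG, HG}, a
973-case/1856-control GWAS with 34% population prevalence (the source
cohort's case fraction), and a differential-response effect of 0.27 log2
units (the magnitude reported at the top locus). Scaled-down choices and
placeholders:

* **n_genes = 2000** (the study analyzed ~11,500) for test speed; the
  responsive fraction is kept at 22% so π1 recovery targets the observed
  regime. With the default noise SDs (replicate 0.25, individual 0.1 log2
  units — placeholders chosen so the study's π1 ≈ 0.22 regime is
  reproduced, not estimates of the real variance components) the measured
  π1 on the default world is 0.229.
* **Genotypes**: dosages are two summed haplotypes, each thresholding an
  AR(1) latent Gaussian (correlation `ld_rho`, default 0.7) at the
  allele-frequency quantile, maf ~ U(0.05, 0.5). This is the simplest
  structure with tunable adjacent-SNP r² for pruning/proxy/HEIDI tests.
  Dichotomization attenuates correlation (tetrachoric effect), strongly so
  for mismatched allele frequencies: latent ρ = 0.9 yields mean adjacent
  dosage r² ≈ 0.34 under the default maf range, and the test suite checks
  the generator against a Monte-Carlo tetrachoric oracle rather than a
  nominal value.
* **Expression**: baseline_g + u_i + β_eQTL·dosage + (response_g +
  γ_gi)·HG + diff_g·HG·PDR + ε, with γ_gi the per-(gene, individual)
  response deviation that makes responses reproducible within individuals.
  Each gene has one causal cis-eQTL; summary statistics are computed over a
  cis window of neighboring SNPs so HEIDI has LD-linked instruments.
  Replicates are exchangeable by default; an optional batch offset exists
  because the source randomized batches.
* **Disease**: liability = b_xy · (centered genetic expression component /
  total expression SD) summed over mediator genes (the
  differential-response genes) + optional direct allele effects + N(0, 1);
  cases/controls are sampled by liability threshold. Scaling by *total*
  expression SD makes the mediation identity b_zy = b_zx·b_xy exact when
  b_zx is per SD of expression, so the planted b_xy = 0.15 is recoverable
  on the liability scale (acceptance-tested to ±0.03). The default GWAS
  model is per-SNP logistic regression on case/control status; a
  `"liability"` option regresses the continuous liability instead, which
  is both the exact-identity scale and vectorizable. Logistic log-odds
  effects exceed liability effects by roughly the logit/probit factor, so
  effect-size recovery tests use the liability scale; conversion to odds
  ratios is out of scope.
* **Pleiotropy**: when requested, a direct liability effect is planted on
  the SNP adjacent to each mediator's causal eQTL, inside the locus where
  HEIDI looks for it.
* All randomness flows from one seed; each stage (panel, expression,
  summary statistics, GSEA, permutation) derives a deterministic sub-seed,
  so stages can be regenerated independently and reruns are byte-identical.

What a green test does **not** establish: the generator has no population
stratification, no batch confounding by default, a single causal eQTL per
gene, exact-normal liability, and rsID-matched tables with no missingness —
so passing tests certify the statistical machinery, not robustness to the
messiness of real cohort data (probe annotation, normalization dialects,
imputation quality, cross-dbSNP matching are all out of scope).

## 7. Known limitations and open choices

* Under the single-causal-eQTL truth model, multi-SNP SMR is *not*
  systematically more powerful than top-SNP SMR (pruned tags add degrees of
  freedom faster than non-centrality); measured head-to-head win rate is
  ~41%. The aggregation argument applies when several independent eQTLs
  exist per gene, which the truth model does not generate.
* The GSEA permutation p floor is ≈ 2/n_perm (same-sign conditioning);
  deeply significant sets need larger n_perm.
* Satterthwaite tails are approximate far beyond α = 0.001.
* The detection filter defaults to "detected in ≥ 1 sample" (permissive,
  configurable); probe-level microarray behaviour is not simulated, so the
  filter is exercised on constructed fixtures only.
* λ_GC near 1 certifies absence of uniform inflation; in the worked example
  λ_GC ≫ 1 because planted association signal is concentrated in the eSNP
  set — a reminder that λ_GC conflates polygenic signal with confounding.
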