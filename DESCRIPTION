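Package: glucoMR
Title: Glucose Transcriptional Response, eQTL-GWAS Enrichment and
    Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("glucoMR", "Developers", email = "glucomr@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline linking interindividual transcriptional
    response to glucose with genetic association. Provides empirical-Bayes
    moderated tests for per-individual glucose response and group-differential
    response, preranked gene-set enrichment with gene-set permutation, Storey
    pi0/pi1 estimation, eSNP-GWAS enrichment with a random-eGene permutation
    null, and summary-data Mendelian randomization (SMR, HEIDI, multi-SNP SMR)
    with LD pruning and proxy lookup. A synthetic-data module generates
    genotype panels with LD, paired standard/high-glucose expression
    experiments, and eQTL/GWAS summary statistics under an expression-mediation
    disease model with full ground truth, so every stage is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
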