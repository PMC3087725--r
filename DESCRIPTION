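Package: admixcohort
Title: Population Structure, QC and Association Workflows for Admixed Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end population-structure analysis for admixed clinical
    cohorts genotyped on SNP arrays: genotype input/output in PLINK and VCF
    formats with multi-cohort merging and allele harmonization; a sample- and
    SNP-level quality-control cascade with exact exclusion accounting
    (call rates, exact Hardy-Weinberg test, differential missingness, batch
    checks, inbreeding and identity-by-descent relatedness, sex check);
    sliding-window LD pruning and delta-statistic selection of
    ancestry-informative markers; global structure by identity-by-state
    multidimensional scaling and genotype PCA; a windowed local-versus-global
    ancestry canonical-correlation scan; maximum-likelihood EM estimation of
    individual admixture proportions; D-prime confidence-interval haplotype
    blocks with per-group haplotype frequencies; and additive single-SNP
    association of log-BMI residuals with principal-component adjustment.
    A synthetic admixed-cohort generator with known ground truth (drift from
    shared ancestral frequencies, Dirichlet admixture, block-wise local
    ancestry, haplotype-pool LD, structured missingness, batch distortion,
    duplicates and relatives) makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
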