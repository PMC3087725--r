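---
title: "Population structure analysis of admixed cohorts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure analysis of admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixcohort` implements the analysis sequence used to characterize the
genetic background of an admixed clinical cohort genotyped on a SNP array:
quality control with exact exclusion accounting, construction of pruned and
ancestry-informative marker sets, global structure by identity-by-state
multidimensional scaling and genotype PCA, a windowed local-versus-global
ancestry scan, maximum-likelihood estimation of individual admixture
proportions, haplotype-block comparison across groups, and additive BMI
association with structure adjustment. Because patient genotypes of this
kind are not publicly deposited, the package pairs every stage with a
synthetic cohort generator whose ground truth makes the stage testable.
This vignette records the models, the parameters that matter, and the
design decisions that were genuinely open.

## The synthetic cohort generator

**Ancestral frequencies and drift.** Each SNP draws an ancestral frequency
`p ~ Uniform(0.05, 0.95)`. Population `k` then drifts under the
Balding-Nichols model: `f_k ~ Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`, so
`E[f_k] = p` and `Var[f_k] = F_k p(1-p)`; `F_k` plays the role of an
FST-like drift parameter. Frequencies are clipped to `[0.01, 0.99]` so no
population is ever fixed. The defaults use two ancestral populations at
`F = 0.15`, a moderate continental-scale differentiation.

**Admixture.** Individual proportions are Dirichlet. The default
three-group design mimics an urban clinical cohort: one group centered at
80% ancestry from population 1 (`alpha = (3.2, 0.8)`), one nearly pure
population 2 (`alpha = (0.25, 4.75)`), and one broadly admixed,
high-variance group (`alpha = (0.7, 1.3)`). These are package choices;
they are stylized, not estimates of any particular cohort.

**Local ancestry.** In `local` mode each haplotype's ancestry along a
chromosome is a Markov process: breakpoints arrive as a Poisson process at
`switch_rate_per_mb` and each segment's ancestry is drawn independently
from the individual's proportions, which are therefore the chain's
stationary distribution. Segment lengths are exponential in Mb, the
standard admixture-LD picture. `switch_rate = 0` degenerates to whole
chromosomes drawn from `q`.

**LD blocks.** With `ld_block_size > 0`, consecutive SNPs form blocks and
each block in each population carries a pool of `n_haplotypes_per_pool`
haplotypes. Pool haplotypes follow an infinite-sites model on a random
genealogy: each SNP mutates exactly once, on a random clade of the pool's
bifurcating tree. Every within-pool SNP pair is therefore compatible with
at most three gametes — the defining property of a haplotype block, and
the reason real blocks show `D' = 1` internally. An earlier draft drew
pool haplotypes as independent Bernoulli vectors; that produces four-gamete
pairs with weak D' inside "blocks" and is not what the block concept
means, so it was replaced. Note that inside pooled blocks the realized
allele frequencies come from clade sizes, not from the drift draw.

**Nuisance order.** Corruptions are injected in a fixed order so that
ground truth is well defined: haplotype pools (part of genotype
generation), MCAR missingness, diagnosis-linked missingness (extra missing
rate at a random SNP subset for flagged samples), batch corruption,
duplicates and parent-child pairs, sex-label mismatches, and finally the
phenotype. Batch corruption is modeled as a cluster-calling shift — at an
affected SNP, a fraction of the bad batch's calls collapses onto the
minor-allele homozygote cluster — because a batch artifact that does not
displace allele frequencies is undetectable by any frequency-based scan.
Duplicates are exact copies placed in a different batch (they exercise
replicate concordance); children receive one transmitted allele per SNP,
guaranteeing identity-by-state of at least 1 wherever the parent is
called. The phenotype uses the pre-corruption dosages of the causal SNPs,
so missingness never feeds back into the trait.

**Phenotype.** `log(BMI) = mu + beta_age * age_std + beta_sex * male +
sum_j beta_j dosage_j + N(0, sigma_env^2)`, stored on the natural scale.
Defaults (`beta_age = 0.05`, `beta_sex = 0.1`, `sigma_env = 0.2`,
`mu = log 28`) give a realistic BMI spread around 28 kg/m².

**What the generator does not emulate:** realistic LD decay with distance,
coalescent recombination maps, genotype-intensity-level artifacts, and
epistasis. Passing tests therefore demonstrate correctness of the
algorithms under a clean generative model, not robustness to every
artifact of real array data.

## Quality control

The cascade applies sample filters first (replicate removal, call rate
greater than 5% missing, sex mismatch), then SNP filters (call rate, MAF
below 0.01, batch-effect scan, differential missingness by diagnosis,
exact HWE at p below 0.001), and finally inbreeding-coefficient outliers
(beyond four standard deviations of the mean). Every step is evaluated on
the survivors of the previous steps and records `(n_before, n_excluded,
n_after)`; `ledger_check()` asserts exact integer conservation and
chaining. Steps whose inputs are absent (a single batch, no diagnosis
flag, no X data) record zero exclusions rather than silently vanishing, so
ledgers from different configurations remain comparable.

The HWE test is the exact conditional test (sum of the probabilities of
all heterozygote configurations no more probable than the observed one,
with a `1 + 1e-9` relative tie tolerance), computed by the stable ratio
recurrence; the test suite checks it against an independent closed-form
enumeration for every margin with up to 200 genotypes. The exact test
rather than chi-square matches the default of the standard QC tool in this
field. HWE is computed on all surviving samples pooled; whether per-group
testing is preferable is left configurable by filtering the cohort first
(in an admixed cohort the pooled test also reacts to the Wahlund effect,
which here is part of the point of the structure analysis that follows).

Differential missingness uses Fisher's exact test at a raw per-SNP
threshold (default `1e-5`) without multiplicity correction, because the
flagged count itself is the quantity of interest; the batch-effect scan,
by contrast, is an allele-count chi-square across batches with a
Bonferroni-corrected family-wise level, since there a single decision
(drop or keep) is taken per SNP. The batch scan is a reconstruction — the
motivating analyses name no method for their batch step.

The IBD estimator is the method-of-moments inversion of observed IBS-state
counts against their expectations given allele frequencies, projected onto
the simplex, without small-sample bias corrections; `pihat = z1/2 + z2`.
It is intended for screening pairs (duplicates near 1, parent-child near
0.5, unrelated near 0), not for precise kinship. All-pairs IBD inside the
cascade would be quadratic in samples, so the cascade exposes
`pihat_max = NULL` by default and relatedness screening is run separately
on suspect pairs.

## Marker sets

Pruning follows the sliding-window rule: within 50-SNP windows, while any
retained pair has `r^2 > 0.2`, remove one member; shift by 5 SNPs; repeat.
Windows slide over the currently retained sequence and passes repeat to a
fixed point, with a final stride-1 sweep covering the offsets the stride
skips; the post-scan contract (no retained within-window pair above the
threshold) therefore holds by construction and is asserted in the tests.
The victim of a high-LD pair is chosen deterministically: higher
missingness, then lower MAF, then later position. Pairwise `r^2` is the
squared Pearson correlation of dosages over samples with both calls
present.

The delta statistic is the sum over the two alleles of the absolute
frequency difference between two reference panels, i.e. `2|p1 - p2|`,
bounded by 2 and invariant to allele orientation. AIM selection keeps
`delta >= delta_min` then prunes. The default `delta_min = 0.3` is a
package choice (a round value that retains strongly informative markers);
it is exposed as a parameter and should be tuned to the panels at hand.

## Global and local structure

IBS similarity is the mean shared-allele fraction over co-called SNPs;
classical (Torgerson) MDS embeds `1 - IBS`. Genotype PCA standardizes each
variant by `sqrt(2 p (1-p))` and mean-imputes missing calls before the
decomposition (the standard choice for genotype PCA; imputation to the
mean adds no structure). Component signs are fixed by making each
loading's largest-magnitude entry positive, so results are reproducible
across BLAS implementations.

The local-vs-global scan tiles autosomes into half-open 20-Mb windows
anchored at 0, computes a local PCA per window with at least 50 SNPs, and
reports the squared largest canonical correlation between the top 10 local
and top 10 global PC score columns (both orthonormalized by QR; the
statistic is invariant to invertible transforms of either basis). A window
whose SNPs carry the genome-wide structure yields rho² near 1; locally
varying ancestry spreads the window distribution. The 50-SNP window
minimum exists because a 10-dimensional local basis estimated from fewer
SNPs is mostly noise.

## Admixture by maximum-likelihood EM

The observation model is binomial: `g_ij ~ Binomial(2, pi_ij)` with
`pi_ij = sum_k q_ik f_kj`, assuming HWE and linkage equilibrium across the
(pruned) markers. The Bayesian MCMC clustering used in the motivating
analyses shares exactly this observation model; this package replaces the
posterior simulation with maximum likelihood via EM, which is tractable at
desk scale and directly testable by parameter recovery. The E-step
attributes each observed allele to an ancestral population; the M-step
renormalizes expected counts. Q rows renormalize to the simplex exactly;
frequencies are clipped to `[1e-6, 1 - 1e-6]`; missing genotypes
contribute no likelihood terms. The log-likelihood is non-decreasing every
iteration (asserted within 1e-9 in the tests).

EM from a random start converges slowly on a plateau where the two
populations are nearly exchangeable, so the first restart uses a spectral
initialization: k-means on the leading principal components, cluster
members starting at 90% ancestry and cluster allele frequencies as `F`.
Further restarts are random. Convergence uses an absolute log-likelihood
gain threshold (`tol`); the recovery experiments run `tol = 0.1` with at
most 150 iterations, which at their problem size (300 samples, ~5000
pruned SNPs) reduces the mean absolute error of recovered proportions well
below the 0.05 acceptance level — additional iterations refine the
likelihood but not the proportions. Component labels are arbitrary:
alignment to a reference (for evaluation only) maximizes summed *signed*
column correlation over permutations, since on the 2-component simplex the
two permutations are indistinguishable by absolute correlation.

`loglik_by_k()` reports the best log-likelihood per K without automatic
selection: the motivating analyses state no selection criterion, so the
table is the deliverable and the elbow is left to the analyst.

## Haplotype blocks

Two-locus haplotype frequencies come from the classical EM over the
double-heterozygote phase ambiguity (relative tolerance 1e-9, at most 1000
iterations). `D' = |p11 - pA pB| / D_max` with the sign-appropriate margin
bound. The confidence interval profiles the multinomial likelihood of the
genotype table over `D'` on a 0.001 grid with margins fixed, normalizes to
unit mass, and reads the 2.5th and 97.5th mass percentiles — the approach
of the standard block-detection tool, reconstructed. Blocks use its
default classification: strong LD when the CI is `[>= 0.70, >= 0.98]`,
strong recombination when the upper bound is below 0.90; a candidate span
needs a strong outermost pair and at least 95% strong among informative
pairs inside; candidates are accepted longest-span-first (ties leftmost)
without overlap. Pairs with MAF below 0.05 are uninformative by default.
Multi-locus block haplotype frequencies use exact EM over phase
configurations, capped at 12 SNPs (4096 haplotypes) — beyond that,
partition the block; samples with any missing call in the block are
dropped from its EM.

## Association

Within each group, log-BMI is residualized on age and sex (female 0, male
1; unknown-sex samples dropped and counted) and the residuals standardized
exactly to mean 0, SD 1. Each SNP is then tested by least squares of the
residual on dosage, optionally with the first two principal components as
covariates (the admixed groups are adjusted; the reference-like group is
not). The two-stage procedure is kept because it matches the motivating
analyses; the statistically cleaner joint model (`log BMI ~ dosage + age +
sex + PCs`) is available via `method = "joint"` and agrees with the
two-stage p-values in ranking. Calibration is quantified by the genomic
inflation factor `lambda = median(t^2)/0.456`; the calibration experiment
uses 5000 SNPs per arm because lambda is a median and its Monte-Carlo
error at smaller SNP counts would be comparable to the calibration band of
interest.

## Problem sizes and reproducibility

The experiments behind the acceptance checks use: admixture recovery at
n = 300, m = 5000 (10 seeds); scan contrast at n = 200, twelve 20-Mb
windows of ~200 SNPs (20 paired seeds); block recovery at n = 400, eight
10-SNP pools (10 seeds); association calibration at n = 500, m = 5000 per
arm. These sizes resolve each property with comfortable margins while
keeping the whole suite runnable on a single CPU in minutes. All
randomness flows from explicit seeds; identical configurations reproduce
byte-identical cohorts and identical fits.

## Known limitations

The EM admixture fit reports maximum-likelihood point estimates, not
posterior uncertainty. The IBD moment estimator omits finite-sample bias
corrections. The D' confidence interval is a normalized likelihood grid,
not a frequentist interval with guaranteed coverage. The generator's
haplotype pools impose block boundaries on a fixed grid and linkage
equilibrium between blocks, which is more clear-cut than real genomes.
Text-format PLINK files carry no allele orientation, so reading them
orients each variant to its minor allele; use the binary format when exact
orientation matters.
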