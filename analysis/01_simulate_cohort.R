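#!/usr/bin/env Rscript
# Stage 1: generate the synthetic three-group admixed cohort that stands in
# for the undeposited patient genotypes, and write it in PLINK binary form
# with its metadata and ground truth. Later stages read these files.
#
# The cohort emulates an urban clinical biobank: two ancestral populations
# at moderate drift; one group drawing most ancestry from each; a third,
# highly variable admixed group; batch structure with a corrupted batch;
# diagnosis-linked missingness; replicate pairs; a parent-child pair; a few
# sex-label errors; an X-like chromosome; and a log-normal BMI with age,
# sex and two SNP effects.

library(admixcohort)

out_dir <- "results/cohort"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(
  n_samples = c(AA = 150, EA = 150, HA = 150),
  m_variants = 6000, n_chromosomes = 4,
  K_true = 2, fst = c(0.15, 0.15),
  alpha = list(AA = c(3.2, 0.8), EA = c(0.25, 4.75), HA = c(0.7, 1.3)),
  missing_rate = 0.01,
  diff_missing = list(flag = "dx1", extra_rate = 0.1, snp_fraction = 0.005),
  batch_distortion = list(n_batches = 3, n_bad_snps = 15, rate = 0.3),
  n_duplicates = 3, n_parent_child_pairs = 1, sex_mismatch_rate = 0.005,
  n_x_snps = 80,
  causal_snps = cbind(c(10, 20), c(0.25, 0.15)),
  seed = 2024
)

sim <- simulate_cohort(cfg)
x <- sim$cohort
print(x)

write_plink(x, file.path(out_dir, "cohort"))
write_metadata(x, file.path(out_dir, "metadata.tsv"))

q <- data.frame(sample_id = x$samples$sample_id,
                group = x$samples$group,
                sim$truth$q_true)
names(q)[-(1:2)] <- paste0("q", seq_len(cfg$K_true))
write.table(q, file.path(out_dir, "ground_truth_admixture.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
freqs <- data.frame(rsid = x$variants$rsid,
                    t(sim$truth$freqs_true))
names(freqs)[-1] <- paste0("pop", seq_len(cfg$K_true))
write.table(freqs, file.path(out_dir, "ground_truth_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("injected nuisances:\n")
str(sim$truth$excluded_truth)
cat("\nwrote PLINK fileset, metadata and ground truth under", out_dir, "\n")
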