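#!/usr/bin/env Rscript
# Stage 3: analysis marker sets. Sliding-window LD pruning (r^2 0.2 in
# 50-SNP windows, 5-SNP step) for the structure analyses, and a second,
# ancestry-informative set selected on the delta statistic between the two
# reference-like groups and then pruned the same way.

library(admixcohort)

out_dir <- "results/markers"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

x <- read_plink("results/qc/cohort_clean")
x <- attach_metadata(x, "results/qc/metadata_clean.tsv")
auto <- subset_cohort(x, variants = is_autosome(x$variants$chrom))

pruned <- ld_prune(auto, window_snps = 50, step_snps = 5, r2_max = 0.2)
print(pruned)
stopifnot(prune_violations(auto, pruned) == 0L)
write_marker_set(pruned, file.path(out_dir, "pruned.txt"))

f1 <- allele_freq(auto$geno[auto$samples$group == "AA", , drop = FALSE])
f2 <- allele_freq(auto$geno[auto$samples$group == "EA", , drop = FALSE])
delta <- delta_statistic(f1, f2)
cat(sprintf("delta: median %.3f, %d SNPs at delta >= 0.3\n",
            median(delta, na.rm = TRUE), sum(delta >= 0.3, na.rm = TRUE)))
aims <- select_aims(auto, delta, delta_min = 0.3)
print(aims)
write_marker_set(aims, file.path(out_dir, "aims.txt"))

write.table(data.frame(rsid = auto$variants$rsid, delta = delta),
            file.path(out_dir, "delta_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("marker sets written under", out_dir, "\n")
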