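# Orchestration: a validated configuration shared by the analysis stages
# and a one-call end-to-end demonstration on simulated data.

default_config <- function() {
  list(
    thresholds = list(
      sample_missing_max = 0.05, snp_missing_max = 0.05, maf_min = 0.01,
      hwe_p_min = 0.001, diff_missing_p_min = 1e-5, batch_p_min = 0.05,
      inbreeding_sd_limit = 4, diff_flag = "dx1"
    ),
    prune = list(window_snps = 50, step_snps = 5, r2_max = 0.2),
    aims = list(delta_min = 0.3),
    scan = list(window_mb = 20, n_pcs = 10, n_snps_min = 50),
    admixture = list(k_min = 2, k_max = 4, n_restarts = 2, seed = 1,
                     tol = 1e-4, max_iter = 300),
    ld = list(maf_min = 0.05),
    association = list(n_pcs = 2, adjusted_groups = character(0))
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with the sections and keys of `default_config()`
#' (thresholds, prune, aims, scan, admixture, ld, association); missing
#' keys take defaults, unknown keys are rejected with the nearest valid
#' key suggested, and type mismatches name the offending key. An empty
#' file yields all defaults.
#'
#' @param path YAML file path.
#' @return the effective configuration list.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_config()
  cfg <- defaults
  for (section in names(user)) {
    if (!section %in% names(defaults)) {
      stop("unknown config section '", section, "'",
           suggest_key(section, names(defaults)))
    }
    for (key in names(user[[section]])) {
      if (!key %in% names(defaults[[section]])) {
        stop("unknown key '", key, "' in section '", section, "'",
             suggest_key(key, names(defaults[[section]])))
      }
      val <- user[[section]][[key]]
      def <- defaults[[section]][[key]]
      if (is.numeric(def) && !is.numeric(val)) {
        stop("key '", key, "' in section '", section,
             "' must be numeric, got ", class(val)[1])
      }
      if (is.character(def) && !is.character(val)) {
        stop("key '", key, "' in section '", section,
             "' must be character, got ", class(val)[1])
      }
      cfg[[section]][[key]] <- val
    }
  }
  cfg
}

suggest_key <- function(key, valid) {
  if (!length(valid)) return("")
  d <- utils::adist(key, valid)
  near <- valid[which.min(d)]
  if (min(d) <= 3) paste0("; did you mean '", near, "'?") else ""
}

#' End-to-end demonstration on a simulated cohort
#'
#' Simulates a three-group admixed cohort with injected nuisances, then
#' runs the full analysis sequence: QC cascade (with ledger check),
#' replicate concordance, LD pruning, AIM selection, IBS/MDS, PCA,
#' local-vs-global scan, admixture across K, continuum sorting, haplotype
#' blocks on a demonstration region, and per-group BMI association with PC
#' adjustment for the admixed groups. All tables are written
#' tab-delimited under `out_dir`. Reruns with the same seed are identical.
#'
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param n_per_group samples per group (default 200).
#' @param m_variants autosomal SNPs (default 20000).
#' @param config configuration list (see [validate_config()]).
#' @return invisibly, a list with the stage results and the report path.
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("demo"),
                     n_per_group = 200, m_variants = 20000,
                     config = default_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- character(0)
  say <- function(...) report <<- c(report, paste0(...))

  cfg <- sim_config(
    n_samples = stats::setNames(rep(n_per_group, 3), c("AA", "EA", "HA")),
    m_variants = m_variants, n_chromosomes = 4,
    K_true = 2, fst = c(0.15, 0.15),
    alpha = list(AA = c(3.2, 0.8), EA = c(0.25, 4.75), HA = c(0.7, 1.3)),
    missing_rate = 0.01,
    diff_missing = list(flag = "dx1", extra_rate = 0.1, snp_fraction = 0.005),
    batch_distortion = list(n_batches = 3, n_bad_snps = max(5, m_variants %/% 400),
                            rate = 0.3),
    n_duplicates = 3, n_parent_child_pairs = 1, sex_mismatch_rate = 0.005,
    n_x_snps = 80,
    causal_snps = cbind(c(10, 20), c(0.25, 0.15)),
    seed = seed
  )
  sim <- simulate_cohort(cfg)
  x <- sim$cohort
  say("simulated cohort: ", nrow(x$geno), " samples x ", ncol(x$geno),
      " variants (seed ", seed, ")")

  conc <- batch_concordance(x)
  say(sprintf("replicate concordance: mean %.4f (sd %.4f) over %d pairs",
              conc$mean, conc$sd, nrow(conc$pairs)))

  th <- do.call(qc_thresholds, config$thresholds)
  qc <- apply_cascade(x, th)
  ledger_check(qc$ledger)
  say("QC ledger (chain-conservation check passed):")
  say(utils::capture.output(print(qc$ledger)))
  utils::write.table(qc$ledger, file.path(out_dir, "qc_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  xq <- qc$cohort

  pruned <- ld_prune(xq, config$prune$window_snps, config$prune$step_snps,
                     config$prune$r2_max)
  say("LD pruning retained ", length(pruned$variant_idx), " of ",
      ncol(xq$geno), " SNPs")
  write_marker_set(pruned, file.path(out_dir, "pruned_markers.txt"))

  # delta panels: allele frequencies of the two reference-like groups
  f_aa <- allele_freq(xq$geno[xq$samples$group == "AA", , drop = FALSE])
  f_ea <- allele_freq(xq$geno[xq$samples$group == "EA", , drop = FALSE])
  delta <- delta_statistic(f_aa, f_ea)
  aims <- select_aims(xq, delta, config$aims$delta_min,
                      config$prune$window_snps, config$prune$step_snps,
                      config$prune$r2_max)
  say("AIM selection retained ", length(aims$variant_idx), " SNPs at delta >= ",
      config$aims$delta_min)
  write_marker_set(aims, file.path(out_dir, "aim_markers.txt"))

  auto_q <- subset_cohort(xq, variants = is_autosome(xq$variants$chrom))
  ibs <- ibs_matrix(auto_q)
  mds <- classical_mds(ibs, n_dims = 4)
  utils::write.table(
    data.frame(sample_id = rownames(mds$points), mds$points),
    file.path(out_dir, "mds_dimensions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  pca <- pca_genotypes(auto_q, markers = prune_to_autosomes(pruned, xq),
                       n_comp = 10)
  utils::write.table(
    data.frame(sample_id = rownames(pca$scores), pca$scores),
    file.path(out_dir, "pca_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  say(sprintf("PCA leading eigenvalues: %s",
              paste(sprintf("%.2f", pca$eig[1:4]), collapse = ", ")))

  scan <- local_global_scan(auto_q, pca$scores,
                            window_mb = config$scan$window_mb,
                            n_pcs = config$scan$n_pcs,
                            n_snps_min = config$scan$n_snps_min)
  utils::write.table(scan, file.path(out_dir, "local_global_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("local/global scan over ", nrow(scan), " windows; rho2 IQR ",
      sprintf("%.4f", stats::IQR(scan$rho2)))

  kr <- config$admixture$k_min:config$admixture$k_max
  lbk <- loglik_by_k(auto_q, prune_to_autosomes(aims, xq), k_range = kr,
                     n_restarts = config$admixture$n_restarts,
                     seed = config$admixture$seed,
                     tol = config$admixture$tol,
                     max_iter = config$admixture$max_iter)
  utils::write.table(lbk, file.path(out_dir, "loglik_by_k.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  model2 <- attr(lbk, "models")[[1]]
  ord <- continuum_sort(model2, 1, auto_q$samples$sample_id)
  q_out <- data.frame(sample_id = auto_q$samples$sample_id,
                      group = auto_q$samples$group, model2$Q)[ord, ]
  utils::write.table(q_out, file.path(out_dir, "admixture_Q_sorted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("admixture fitted for K = ", paste(kr, collapse = ", "),
      "; loglik: ", paste(sprintf("%.0f", lbk$loglik), collapse = ", "))

  region <- which(auto_q$variants$chrom == auto_q$variants$chrom[1])
  region <- region[seq_len(min(40, length(region)))]
  cmp <- compare_groups(auto_q, region,
                        focal_rsid = auto_q$variants$rsid[region[5]],
                        params = list(maf_min = config$ld$maf_min))
  utils::write.table(cmp$summary, file.path(out_dir, "ld_blocks_by_group.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("LD blocks per group: ",
      paste(cmp$summary$group, cmp$summary$n_blocks, sep = "=",
            collapse = ", "))

  assoc <- list()
  for (gname in unique(auto_q$samples$group)) {
    adj <- gname %in% config$association$adjusted_groups ||
      gname %in% c("AA", "HA")   # admixed groups PC-adjusted by default
    grp_rows <- auto_q$samples$group == gname
    grp_pca <- pca_genotypes(subset_cohort(auto_q, samples = grp_rows),
                             markers = NULL, n_comp = config$association$n_pcs)
    grp <- subset_cohort(auto_q, samples = grp_rows)
    assoc[[gname]] <- bmi_association(
      grp, gname, markers = causal_region_markers(grp),
      pcs = if (adj) grp_pca else NULL, n_pcs = config$association$n_pcs)
  }
  assoc <- do.call(rbind, assoc)
  utils::write.table(assoc, file.path(out_dir, "bmi_association.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("BMI association computed for ", length(unique(assoc$group)),
      " groups on ", length(unique(assoc$rsid)), " candidate SNPs")

  report_path <- file.path(out_dir, "report.txt")
  writeLines(report, report_path)
  invisible(list(cohort = x, qc = qc, pruned = pruned, aims = aims,
                 mds = mds, pca = pca, scan = scan, loglik_by_k = lbk,
                 blocks = cmp, association = assoc, report = report_path))
}

# restrict a marker set to autosomal variants of the source cohort
prune_to_autosomes <- function(ms, x) {
  auto <- which(is_autosome(x$variants$chrom))
  keep <- ms$variant_idx %in% auto
  # re-express indices in the autosome-only cohort
  idx <- match(ms$variant_idx[keep], auto)
  marker_set(ms$name, idx, ms$rsid[keep],
             modifyList(ms$provenance, list(n_after = sum(keep))))
}

# first 30 autosomal SNPs as the demonstration candidate region
causal_region_markers <- function(x) {
  idx <- seq_len(min(30, ncol(x$geno)))
  marker_set("candidate_region", idx, x$variants$rsid[idx],
             list(method = "demo_region", parameters = list(),
                  n_before = ncol(x$geno), n_after = length(idx)))
}
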