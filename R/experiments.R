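# Self-contained calibration and recovery experiments on simulated cohorts.
# Each function regenerates its inputs from a seed and measures one
# property of the pipeline; they back both the test suite and the
# acceptance script. Problem sizes are chosen to resolve each property
# comfortably at desk scale (the vignette discusses the choices).

#' Brute-force enumeration reference for the HWE exact test
#'
#' Independent of the recurrence implementation: computes the exact
#' conditional distribution of the heterozygote count directly from the
#' closed-form multinomial expression
#' `P(h) = n! / (n_AA! h! n_BB!) * 2^h * r! (2n-r)! / (2n)!` via `lgamma`,
#' and the p-value as the mass of configurations no more probable than the
#' observed one (same tie rule as [hwe_exact_test()]).
#'
#' @param n_aa,n_ab,n_bb genotype counts.
#' @return the enumeration p-value.
#' @export
hwe_enumeration_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab                # counted-allele copies
  r <- min(na, 2 * n - na)
  if (r == 0) return(1)
  hs <- seq.int(r %% 2, r, by = 2L)
  log_p <- vapply(hs, function(h) {
    hom_r <- (r - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(r + 1) + lgamma(2 * n - r + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(log_p - max(log_p))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hs)]
  min(sum(probs[probs <= p_obs * (1 + 1e-9)]), 1)
}

#' Exhaustive HWE implementation-vs-enumeration comparison
#'
#' For every genotype-table margin with at most `max_n` individuals and
#' every admissible heterozygote count, compares the implementation's
#' p-value with the closed-form enumeration reference.
#'
#' @param max_n largest table total screened (default 200).
#' @return list: `max_abs_diff`, `n_tables`.
#' @export
hwe_exhaustive_check <- function(max_n = 200) {
  worst <- 0
  n_tables <- 0L
  # p-values for a whole margin at once: sort the distribution and read the
  # cumulative mass at each configuration's (tie-tolerant) probability
  tail_mass <- function(probs) {
    ord <- order(probs)
    cum <- cumsum(probs[ord])
    k <- findInterval(probs * (1 + 1e-9), probs[ord])
    pmin(cum[k], 1)
  }
  for (n in 1:max_n) {
    for (r in 0:n) {                    # rare-allele copies
      if (r == 0) {
        n_tables <- n_tables + 1L
        next
      }
      hs <- seq.int(r %% 2, r, by = 2L)
      # implementation route: recurrence distribution + tie rule
      p_impl <- tail_mass(hwe_het_distribution(n, r)$prob)
      # enumeration route: closed-form multinomial via lgamma
      hom_r <- (r - hs) / 2
      hom_c <- n - hs - hom_r
      log_p <- lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hs + 1) -
        lgamma(hom_c + 1) + hs * log(2) +
        lgamma(r + 1) + lgamma(2 * n - r + 1) - lgamma(2 * n + 1)
      probs <- exp(log_p - max(log_p))
      p_ref <- tail_mass(probs / sum(probs))
      worst <- max(worst, max(abs(p_impl - p_ref)))
      n_tables <- n_tables + length(hs)
    }
  }
  list(max_abs_diff = worst, n_tables = n_tables)
}

#' Admixture-proportion recovery experiment
#'
#' Simulates a two-way admixed cohort (drift 0.2, flat Dirichlet), LD-prunes
#' the markers, fits the EM admixture model at K = 2 and reports the mean
#' absolute error of the estimated proportions after component alignment.
#'
#' @param seed simulation and fitting seed.
#' @param n samples (default 300).
#' @param m SNPs before pruning (default 5000).
#' @return list: `mae`, `n_markers`, `trace` (EM log-likelihoods),
#'   `model`.
#' @export
experiment_admixture_recovery <- function(seed, n = 300, m = 5000) {
  cfg <- sim_config(n_samples = c(pool = n), m_variants = m,
                    n_chromosomes = 4, K_true = 2, fst = c(0.2, 0.2),
                    alpha = list(pool = c(1, 1)), missing_rate = 0,
                    n_x_snps = 0, seed = seed)
  sim <- simulate_cohort(cfg)
  pruned <- ld_prune(sim$cohort)
  model <- admixture_em(sim$cohort, pruned, K = 2, n_restarts = 1,
                        seed = seed, tol = 0.1, max_iter = 150)
  aligned <- align_admixture(model, sim$truth$q_true)
  list(mae = aligned$mae, n_markers = length(pruned$variant_idx),
       trace = model$trace, model = model)
}

#' Local-vs-global scan contrast experiment
#'
#' Paired simulation at one seed: the same configuration in local-ancestry
#' mode and in global mode. Reports the inter-window IQR of the squared
#' canonical correlation in each mode; locally varying ancestry should
#' spread the windows more.
#'
#' @param seed simulation seed.
#' @param n samples (default 200).
#' @param m SNPs (default 2400 over two 120-Mb chromosomes, i.e. twelve
#'   20-Mb windows of ~200 SNPs).
#' @return list: `iqr_local`, `iqr_global`, `scan_local`, `scan_global`.
#' @export
experiment_scan_contrast <- function(seed, n = 200, m = 2400) {
  run_mode <- function(mode) {
    cfg <- sim_config(n_samples = c(pool = n), m_variants = m,
                      n_chromosomes = 2, chrom_length_bp = 1.2e8,
                      K_true = 2, fst = c(0.2, 0.2),
                      alpha = list(pool = c(1, 1)),
                      ancestry_mode = mode, switch_rate_per_mb = 0.1,
                      missing_rate = 0, n_x_snps = 0, seed = seed)
    sim <- simulate_cohort(cfg)
    pca <- pca_genotypes(sim$cohort, n_comp = 10)
    local_global_scan(sim$cohort, pca$scores, window_mb = 20, n_pcs = 10,
                      n_snps_min = 50)
  }
  scan_local <- run_mode("local")
  scan_global <- run_mode("global")
  list(iqr_local = stats::IQR(scan_local$rho2),
       iqr_global = stats::IQR(scan_global$rho2),
       scan_local = scan_local, scan_global = scan_global)
}

#' Haplotype-block boundary recovery experiment
#'
#' Simulates one population whose chromosome is organized into
#' haplotype-pool blocks of `block_size` SNPs, detects blocks with the
#' confidence-interval method, and scores recovery as the mean over true
#' blocks of the best Jaccard index of SNP membership (computed over SNPs
#' passing the detector's MAF gate).
#'
#' @param seed simulation seed.
#' @param n samples (default 400).
#' @param n_blocks true blocks (default 8).
#' @param block_size SNPs per block (default 10).
#' @return list: `jaccard` (mean best-match), `n_detected`, `blocks`.
#' @export
experiment_block_recovery <- function(seed, n = 400, n_blocks = 8,
                                      block_size = 10) {
  m <- n_blocks * block_size
  cfg <- sim_config(n_samples = c(pool = n), m_variants = m,
                    n_chromosomes = 1, chrom_length_bp = 2e6,
                    K_true = 1, fst = 0.2, alpha = list(pool = 1),
                    ld_block_size = block_size, n_haplotypes_per_pool = 6,
                    missing_rate = 0, n_x_snps = 0, seed = seed)
  sim <- simulate_cohort(cfg)
  x <- sim$cohort
  p <- allele_freq(x)
  informative <- which(!is.na(p) & pmin(p, 1 - p) >= 0.05)
  detected <- gabriel_blocks(x, seq_len(m))
  true_members <- split(seq_len(m), (seq_len(m) - 1) %/% block_size)
  jac <- vapply(true_members, function(tm) {
    tm <- intersect(tm, informative)
    if (!length(tm)) return(NA_real_)
    best <- 0
    for (b in detected) {
      dm <- intersect(b$snps, informative)
      j <- length(intersect(tm, dm)) / length(union(tm, dm))
      best <- max(best, j)
    }
    best
  }, numeric(1))
  list(jaccard = mean(jac, na.rm = TRUE), n_detected = length(detected),
       blocks = detected)
}

#' Association calibration experiment
#'
#' Null arm: one unstructured population with a null phenotype; reports
#' the Kolmogorov-Smirnov uniformity p-value of the association p-values
#' and the genomic inflation factor. Stratified arm: two diverged
#' populations pooled, with a population-linked shift added to log-BMI;
#' reports the inflation factor unadjusted and with two principal
#' components.
#'
#' @param seed simulation seed.
#' @param n_null,m_null null-arm size (default 500 x 5000).
#' @param n_strat,m_strat stratified-arm size (default 500 x 5000; the
#'   inflation factor is a median over per-SNP statistics, so its
#'   Monte-Carlo error shrinks with the SNP count).
#' @return list: `ks_p`, `lambda_null`, `lambda_unadjusted`,
#'   `lambda_adjusted`.
#' @export
experiment_assoc_calibration <- function(seed, n_null = 500, m_null = 5000,
                                         n_strat = 500, m_strat = 5000) {
  # --- null arm ---
  cfg0 <- sim_config(n_samples = c(pool = n_null), m_variants = m_null,
                     n_chromosomes = 4, K_true = 1, fst = 0.2,
                     alpha = list(pool = 1), missing_rate = 0,
                     n_x_snps = 0, sigma_env = 0.2, seed = seed)
  sim0 <- simulate_cohort(cfg0)
  br0 <- bmi_residuals(sim0$cohort, "pool")
  a0 <- snp_association(sim0$cohort, br0$residuals)
  ks_p <- stats::ks.test(a0$p[!is.na(a0$p)], "punif")$p.value
  lambda_null <- genomic_lambda(a0)

  # --- stratified arm ---
  half <- n_strat %/% 2
  cfg1 <- sim_config(n_samples = c(p1 = half, p2 = n_strat - half),
                     m_variants = m_strat, n_chromosomes = 4,
                     K_true = 2, fst = c(0.2, 0.2),
                     alpha = list(p1 = c(20, 1), p2 = c(1, 20)),
                     missing_rate = 0, n_x_snps = 0, sigma_env = 0.2,
                     seed = seed + 1)
  sim1 <- simulate_cohort(cfg1)
  x1 <- sim1$cohort
  # population-linked phenotype shift (0.3 log-units along ancestry)
  x1$samples$bmi <- exp(log(x1$samples$bmi) + 0.3 * sim1$truth$q_true[, 1])
  x1$samples$group <- "pool"
  br1 <- bmi_residuals(x1, "pool")
  a_unadj <- snp_association(x1, br1$residuals)
  pca1 <- pca_genotypes(x1, n_comp = 2)
  a_adj <- snp_association(x1, br1$residuals, pcs = pca1, n_pcs = 2)
  list(ks_p = ks_p, lambda_null = lambda_null,
       lambda_unadjusted = genomic_lambda(a_unadj),
       lambda_adjusted = genomic_lambda(a_adj))
}
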