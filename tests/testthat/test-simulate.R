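test_that("identical configurations give bit-identical cohorts", {
  cfg <- sim_config(n_samples = c(A = 20, B = 20), m_variants = 100,
                    n_chromosomes = 2, K_true = 2, fst = c(0.2, 0.2),
                    alpha = list(A = c(2, 1), B = c(1, 2)),
                    missing_rate = 0.02, n_x_snps = 30, n_duplicates = 1,
                    sex_mismatch_rate = 0.05, causal_snps = cbind(3, 0.2),
                    seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$geno, s2$cohort$geno)
  expect_identical(s1$cohort$samples, s2$cohort$samples)
  expect_identical(s1$truth$q_true, s2$truth$q_true)
})

test_that("drift model: population frequencies center on the ancestral mean with variance F p (1-p)", {
  cfg <- sim_config(n_samples = c(A = 2), m_variants = 20000,
                    K_true = 2, fst = c(0.2, 1e-12),
                    alpha = list(A = c(1, 1)), seed = 5)
  set.seed(5)
  f <- simulate_frequencies(cfg, m = 20000)
  p <- attr(f, "ancestral")
  # Beta mean identity: E[f | p] = p
  expect_lt(abs(mean(f[1, ] - p)), 0.01)
  # F -> 0 limit: frequencies collapse onto the ancestral values
  expect_lt(max(abs(f[2, ] - pmin(pmax(p, 0.01), 0.99))), 1e-4)
  # Beta variance identity: Var[f | p] = F p (1 - p), up to clipping loss
  v_obs <- mean((f[1, ] - p)^2)
  v_exp <- 0.2 * mean(p * (1 - p))
  expect_lt(abs(v_obs - v_exp) / v_exp, 0.1)
  expect_true(all(f >= 0.01 & f <= 0.99))
})

test_that("admixture proportions have the Dirichlet mean and rows sum to one", {
  sim <- quick_sim(seed = 3, n = 1500, m = 10, alpha = c(2, 6))
  q <- sim$truth$q_true
  expect_equal(rowSums(q), rep(1, nrow(q)), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(q) - c(0.25, 0.75))), 0.02)
})

test_that("a degenerate Dirichlet collapses the cohort to one population", {
  sim <- quick_sim(seed = 4, n = 50, m = 200, alpha = c(100, 0.01))
  expect_gt(min(sim$truth$q_true[, 1]), 0.99)
})

test_that("duplicates are exact copies and parent-child pairs share an allele at every co-called SNP", {
  cfg <- sim_config(n_samples = c(A = 30), m_variants = 150,
                    n_chromosomes = 1, K_true = 2, fst = c(0.2, 0.2),
                    alpha = list(A = c(1, 1)), missing_rate = 0,
                    n_duplicates = 1, n_parent_child_pairs = 1,
                    n_x_snps = 20, seed = 8)
  sim <- simulate_cohort(cfg)
  x <- sim$cohort
  dup <- sim$truth$excluded_truth$duplicate_pairs
  g_a <- x$geno[dup[1, 1], ]
  g_b <- x$geno[dup[1, 2], ]
  expect_identical(g_a, g_b)
  pc <- sim$truth$excluded_truth$parent_child_pairs
  auto <- is_autosome(x$variants$chrom)
  d_par <- x$geno[pc[1, 1], auto]
  d_kid <- x$geno[pc[1, 2], auto]
  both <- !is.na(d_par) & !is.na(d_kid)
  ibs <- 2 - abs(d_par[both] - d_kid[both])
  expect_true(all(ibs >= 1))
})

test_that("local mode with zero switch rate assigns whole chromosomes to one population", {
  cfg <- sim_config(n_samples = c(A = 10), m_variants = 100,
                    n_chromosomes = 2, K_true = 2, fst = c(0.2, 0.2),
                    alpha = list(A = c(1, 1)), ancestry_mode = "local",
                    switch_rate_per_mb = 0, missing_rate = 0,
                    n_x_snps = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  anc <- sim$truth$local_ancestry$hap1
  chrom <- sim$cohort$variants$chrom
  for (ch in unique(chrom)) {
    per_chr <- anc[, chrom == ch, drop = FALSE]
    expect_true(all(apply(per_chr, 1, function(r) length(unique(r)) == 1)))
  }
})

test_that("haplotype-pool blocks create higher within-block than between-block D-prime", {
  cfg <- sim_config(n_samples = c(A = 250), m_variants = 30,
                    n_chromosomes = 1, chrom_length_bp = 1e6, K_true = 1,
                    fst = 0.2, alpha = list(A = 1), ld_block_size = 10,
                    n_haplotypes_per_pool = 6, missing_rate = 0,
                    n_x_snps = 0, seed = 10)
  sim <- simulate_cohort(cfg)
  ld <- pairwise_ld(sim$cohort, 1:30)
  blk <- function(i) (i - 1) %/% 10
  within <- blk(ld$idx1) == blk(ld$idx2)
  expect_gt(mean(ld$dprime[within]), mean(ld$dprime[!within]) + 0.3)
})

test_that("phenotype model: null parameters give constant BMI and age effect propagates its sign", {
  cfg0 <- sim_config(n_samples = c(A = 40), m_variants = 20, K_true = 1,
                     fst = 0.1, alpha = list(A = 1), beta_age = 0,
                     beta_sex = 0, sigma_env = 0, missing_rate = 0,
                     n_x_snps = 0, seed = 1)
  sim0 <- simulate_cohort(cfg0)
  expect_equal(sim0$cohort$samples$bmi,
               rep(exp(cfg0$bmi_mu), 40), tolerance = 1e-12)

  cfg1 <- sim_config(n_samples = c(A = 800), m_variants = 20, K_true = 1,
                     fst = 0.1, alpha = list(A = 1), beta_age = -0.1,
                     beta_sex = 0, sigma_env = 0.05, missing_rate = 0,
                     n_x_snps = 0, seed = 2)
  sim1 <- simulate_cohort(cfg1)
  s <- sim1$cohort$samples
  expect_lt(cor(log(s$bmi), s$age), -0.5)
})

test_that("a simulated causal SNP is recovered by the association stage", {
  hits <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_samples = c(A = 1000), m_variants = 50,
                      n_chromosomes = 1, K_true = 1, fst = 0.1,
                      alpha = list(A = 1), missing_rate = 0, n_x_snps = 0,
                      causal_snps = cbind(5, 0.25), sigma_env = 0.3,
                      seed = seed)
    sim <- simulate_cohort(cfg)
    br <- bmi_residuals(sim$cohort, "A")
    a <- snp_association(sim$cohort, br$residuals)
    a$beta[5] > 0 && a$p[5] < 1e-3
  }, logical(1))
  expect_gte(sum(hits), 8)
})

test_that("out-of-range causal index and malformed alpha are rejected", {
  expect_error(sim_config(n_samples = c(A = 10), m_variants = 20,
                          K_true = 1, fst = 0.1, alpha = list(A = 1),
                          causal_snps = cbind(21, 0.2)),
               "out of range")
  expect_error(sim_config(n_samples = c(A = 10), K_true = 2,
                          fst = c(0.1, 0.1), alpha = list(A = c(1, 2, 3))),
               "length K_true")
})
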