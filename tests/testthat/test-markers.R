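test_that("genotype r2 matches a hand computation and is sign-insensitive", {
  x <- c(0, 1, 2, 0, 1, 2)
  y <- c(0, 0, 2, 0, 2, 2)
  # independent arithmetic: explicit sums
  n <- 6
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  expect_equal(genotype_r2(x, y), sxy^2 / (sxx * syy))
  expect_equal(genotype_r2(x, x), 1)
  expect_equal(genotype_r2(x, 2 - x), 1)
  # monomorphic on the complete overlap -> undefined
  expect_true(is.na(genotype_r2(c(1, 1, 1, NA), c(0, 1, 2, 0))))
  expect_true(is.na(genotype_r2(c(0, NA, NA, 1), c(NA, 0, 1, NA))))
})

test_that("a perfect-LD clique is pruned down to a single representative", {
  set.seed(31)
  base <- sample(0:2, 80, replace = TRUE)
  geno <- matrix(rep(base, 12), ncol = 12)
  geno <- cbind(geno, matrix(sample(0:2, 80 * 8, replace = TRUE), ncol = 8))
  x <- tiny_cohort(geno)
  ms <- ld_prune(x, window_snps = 10, step_snps = 2, r2_max = 0.2)
  expect_identical(sum(ms$variant_idx <= 12), 1L)
  expect_identical(prune_violations(x, ms, 10, 0.2), 0L)
})

test_that("pruning is idempotent and chromosome-local", {
  sim <- quick_sim(seed = 32, n = 150, m = 400)
  x <- sim$cohort
  ms1 <- ld_prune(x, window_snps = 20, step_snps = 5, r2_max = 0.2)
  sub <- subset_cohort(x, variants = ms1$variant_idx)
  ms2 <- ld_prune(sub, window_snps = 20, step_snps = 5, r2_max = 0.2)
  expect_identical(length(ms2$variant_idx), length(ms1$variant_idx))
  expect_identical(sub$variants$rsid[ms2$variant_idx], ms1$rsid)

  # chromosome independence: pruning with chr2 present removes the same
  # chr1 SNPs as pruning chr1 alone
  chr1 <- x$variants$chrom == "1"
  ms_all <- ld_prune(x, 20, 5, 0.2)
  ms_chr1 <- ld_prune(subset_cohort(x, variants = chr1), 20, 5, 0.2)
  expect_identical(intersect(ms_all$rsid, x$variants$rsid[chr1]),
                   ms_chr1$rsid)
})

test_that("variants in linkage equilibrium are mostly retained", {
  sim <- quick_sim(seed = 33, n = 500, m = 600, K = 1, alpha = 1,
                   fst = 0.15)
  ms <- ld_prune(sim$cohort)
  expect_gte(length(ms$variant_idx) / 600, 0.95)
})

test_that("the pruning contract holds on data with real LD blocks", {
  cfg <- sim_config(n_samples = c(A = 200), m_variants = 300,
                    n_chromosomes = 2, K_true = 1, fst = 0.15,
                    alpha = list(A = 1), ld_block_size = 10,
                    n_haplotypes_per_pool = 6, missing_rate = 0.01,
                    n_x_snps = 0, seed = 34)
  sim <- simulate_cohort(cfg)
  ms <- ld_prune(sim$cohort)
  expect_lt(length(ms$variant_idx), 300)
  expect_identical(prune_violations(sim$cohort, ms), 0L)
})

test_that("delta statistic is twice the frequency difference, symmetric, allele-invariant", {
  expect_equal(delta_statistic(0.8, 0.3), 1.0)
  expect_equal(delta_statistic(0.4, 0.4), 0)
  expect_equal(delta_statistic(1, 0), 2)
  p1 <- runif(20)
  p2 <- runif(20)
  expect_equal(delta_statistic(p1, p2), delta_statistic(p2, p1))
  # counting the other allele at both panels leaves delta unchanged
  expect_equal(delta_statistic(1 - p1, 1 - p2), delta_statistic(p1, p2))
  expect_true(is.na(delta_statistic(NA, 0.5)))
})

test_that("AIM selection keeps high-delta variants and then prunes", {
  sim <- quick_sim(seed = 35, n = 200, m = 500, fst = 0.25)
  x <- sim$cohort
  freqs <- sim$truth$freqs_true
  delta <- delta_statistic(freqs[1, seq_len(ncol(x$geno))],
                           freqs[2, seq_len(ncol(x$geno))])
  aims <- select_aims(x, delta, delta_min = 0.3)
  sel <- seq_len(ncol(x$geno)) %in% aims$variant_idx
  expect_gt(mean(delta[sel]), mean(delta[!sel]))
  expect_true(all(delta[sel] >= 0.3))
  # delta_min = 0 reduces to plain pruning
  aims0 <- select_aims(x, delta, delta_min = 0)
  plain <- ld_prune(x)
  expect_identical(aims0$rsid, plain$rsid)
  expect_error(select_aims(x, delta, delta_min = 2.5), "no variants")
})

test_that("an AIM panel beats an equally sized random pruned panel at ancestry recovery", {
  sim <- quick_sim(seed = 36, n = 150, m = 1200, fst = 0.2)
  x <- sim$cohort
  m <- ncol(x$geno)
  freqs <- sim$truth$freqs_true
  delta <- delta_statistic(freqs[1, seq_len(m)], freqs[2, seq_len(m)])
  aims <- select_aims(x, delta, delta_min = 0.3)
  k <- length(aims$variant_idx)
  plain <- ld_prune(x)
  set.seed(36)
  rand_idx <- sort(sample(plain$variant_idx, k))
  rand_ms <- structure(list(name = "rand", variant_idx = rand_idx,
                            rsid = x$variants$rsid[rand_idx],
                            provenance = list()), class = "marker_set")
  mae_for <- function(ms) {
    fit <- admixture_em(x, ms, K = 2, n_restarts = 1, seed = 1,
                        tol = 0.1, max_iter = 80)
    align_admixture(fit, sim$truth$q_true)$mae
  }
  expect_lt(mae_for(aims), mae_for(rand_ms))
})
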