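test_that("call rates use full-matrix denominators", {
  g <- matrix(0L, 4, 5)
  g[1, ] <- NA
  g[2, 1:3] <- NA
  g[, 5] <- c(NA, NA, NA, 0L)
  x <- tiny_cohort(g)
  cr <- call_rates(x)
  expect_equal(unname(cr$sample), c(1, 0.6 + 0.2, 0.2, 0))
  expect_equal(unname(cr$snp[5]), 0.75)
  expect_equal(unname(cr$snp[1]), 0.5)
  expect_equal(unname(cr$snp[4]), 0.25)
  cr0 <- call_rates(tiny_cohort(matrix(1L, 3, 3)))
  expect_true(all(cr0$sample == 0) && all(cr0$snp == 0))
})

test_that("differential missingness agrees with the hypergeometric tail", {
  # 2x2 table: flagged class 10 missing / 40 called, other 0 / 50
  g <- matrix(0L, 100, 1)
  g[1:10, 1] <- NA
  flag <- rep(c(TRUE, FALSE), each = 50)
  x <- tiny_cohort(g)
  p <- differential_missingness(x, flag)
  # enumeration oracle: two-sided Fisher = sum of tables as or more extreme
  oracle <- sum(dhyper(0:10, 10, 90, 50)[
    dhyper(0:10, 10, 90, 50) <= dhyper(10, 10, 90, 50) * (1 + 1e-7)])
  expect_equal(p, oracle, tolerance = 1e-9)
  # identical missingness in both classes
  g2 <- matrix(0L, 100, 2)
  g2[c(1:5, 51:55), 1] <- NA
  p2 <- differential_missingness(tiny_cohort(g2), flag)
  expect_equal(unname(p2), c(1, 1))
})

test_that("replicate concordance counts equal co-called calls", {
  sim <- quick_sim(seed = 20, n = 40, m = 500, n_duplicates = 2,
                   missing_rate = 0.01)
  bc <- batch_concordance(sim$cohort)
  expect_identical(nrow(bc$pairs), 2L)
  expect_equal(bc$mean, 1)
  # flip 1% of one copy's calls
  x <- sim$cohort
  rep_id <- x$samples$sample_id[x$samples$is_replicate][1]
  row <- match(rep_id, x$samples$sample_id)
  called <- which(!is.na(x$geno[row, ]))
  flip <- called[seq_len(5)]
  x$geno[row, flip] <- (x$geno[row, flip] + 1L) %% 3L
  bc2 <- batch_concordance(x)
  pair <- bc2$pairs[bc2$pairs$id2 == rep_id, ]
  expect_equal(pair$concordance, 1 - 5 / length(called), tolerance = 1e-9)
})

test_that("batch scan flags corrupted SNPs and is silent across identical batches", {
  cfg <- sim_config(n_samples = c(A = 500), m_variants = 300,
                    n_chromosomes = 1, K_true = 1, fst = 0.15,
                    alpha = list(A = 1), missing_rate = 0, n_x_snps = 0,
                    batch_distortion = list(n_batches = 2, n_bad_snps = 50,
                                            rate = 0.3),
                    seed = 21)
  sim <- simulate_cohort(cfg)
  bs <- batch_effect_scan(sim$cohort)
  bad <- match(sim$truth$excluded_truth$batch_snps,
               sim$cohort$variants$rsid)
  expect_gte(mean(bs$flagged[bad]), 0.9)
  expect_lte(sum(bs$flagged[-bad]), 2)

  # duplicate the cohort into two identical "batches"
  x <- tiny_cohort(matrix(rep(c(0L, 1L, 2L, 1L), 5), 4, 5))
  x$samples$batch <- c("b1", "b1", "b2", "b2")
  x$geno[3:4, ] <- x$geno[1:2, ]
  bs2 <- batch_effect_scan(x)
  expect_true(all(bs2$p == 1))
  x$samples$batch <- "b1"
  expect_error(batch_effect_scan(x), "2 batches")
})

test_that("inbreeding coefficient is near zero under HWE, one for full homozygotes, positive under Wahlund mixing", {
  sim <- quick_sim(seed = 22, n = 500, m = 10000, K = 1, alpha = 1,
                   fst = 0.15)
  f <- inbreeding_coefficient(sim$cohort)
  expect_lt(abs(mean(f)), 0.01)

  x <- sim$cohort
  x$geno[1, ] <- ifelse(x$geno[1, ] == 1L, 2L, x$geno[1, ])
  expect_equal(inbreeding_coefficient(x)[1], 1)

  # Wahlund: pool two diverged populations without mixing
  sim2 <- quick_sim(seed = 23, n = 400, m = 4000, K = 2,
                    alpha = c(0.02, 0.02), fst = 0.25)
  f2 <- inbreeding_coefficient(sim2$cohort)
  expect_gt(mean(f2), 0.05)
})

test_that("IBD estimates separate duplicates, parent-child pairs and unrelated pairs", {
  cfg <- sim_config(n_samples = c(A = 12), m_variants = 20000,
                    n_chromosomes = 4, K_true = 1, fst = 0.1,
                    alpha = list(A = 1), missing_rate = 0, n_x_snps = 0,
                    n_duplicates = 1, n_parent_child_pairs = 1, seed = 24)
  sim <- simulate_cohort(cfg)
  x <- sim$cohort
  freqs <- sim$truth$freqs_true[1, seq_len(sum(is_autosome(x$variants$chrom)))]
  dup <- sim$truth$excluded_truth$duplicate_pairs[1, ]
  pc <- sim$truth$excluded_truth$parent_child_pairs[1, ]
  pairs <- rbind(dup, pc, c(x$samples$sample_id[1], x$samples$sample_id[2]))
  est <- ibd_estimate(x, freqs = freqs, pairs = pairs)
  expect_gte(est$pihat[1], 0.95)
  expect_lt(abs(est$pihat[2] - 0.5), 0.05)
  expect_gt(est$z1[2], est$z0[2])
  expect_gt(est$z1[2], est$z2[2])
  expect_lt(est$pihat[3], 0.1)
  expect_false(any(est$unreliable))
  expect_equal(est$z0 + est$z1 + est$z2, rep(1, 3), tolerance = 1e-12)
})

test_that("sex check infers hemizygous males and HWE females, flagging declared mismatches", {
  cfg <- sim_config(n_samples = c(A = 120), m_variants = 30, K_true = 1,
                    fst = 0.1, alpha = list(A = 1), missing_rate = 0,
                    n_x_snps = 60, seed = 25)
  sim <- simulate_cohort(cfg)
  x <- sim$cohort
  sc <- sex_check(x)
  male <- x$samples$sex == "male"
  expect_gt(min(sc$x_het_f[male]), 0.8)   # hemizygotes have no heterozygotes
  expect_lt(median(sc$x_het_f[!male]), 0.1)
  expect_false(any(sc$mismatch))
  x$samples$sex[1] <- ifelse(male[1], "female", "male")
  sc2 <- sex_check(x)
  expect_true(sc2$mismatch[1])
  expect_identical(sum(sc2$mismatch), 1L)
})

test_that("cascade with lenient thresholds is the identity and its ledger chains", {
  # low drift and n = 200 keep every SNP safely polymorphic
  sim <- quick_sim(seed = 26, n = 200, m = 200, fst = 0.05,
                   missing_rate = 0)
  th <- qc_thresholds(sample_missing_max = 0.99, snp_missing_max = 0.99,
                      maf_min = 1e-6, hwe_p_min = 1e-12,
                      inbreeding_sd_limit = 100)
  out <- apply_cascade(sim$cohort, th)
  expect_true(all(out$ledger$n_excluded == 0))
  expect_identical(out$cohort$geno, sim$cohort$geno)
  expect_true(ledger_check(out$ledger))
})

test_that("fully missing SNPs are removed exactly at the SNP-missingness step", {
  # 10 dead SNPs of 300 keep per-sample missingness under the 5% cap
  sim <- quick_sim(seed = 27, n = 50, m = 300, missing_rate = 0)
  x <- sim$cohort
  x$geno[, 11:20] <- NA_integer_
  out <- apply_cascade(x, qc_thresholds())
  row <- out$ledger[out$ledger$step == "snp_call_rate", ]
  expect_identical(row$n_excluded, 10L)
  expect_false(any(x$variants$rsid[11:20] %in% out$cohort$variants$rsid))
})

test_that("permuting sample order changes no cascade counts", {
  sim <- quick_sim(seed = 28, n = 80, m = 300, missing_rate = 0.03,
                   n_x_snps = 40)
  x <- sim$cohort
  set.seed(1)
  perm <- sample(nrow(x$geno))
  xp <- subset_cohort(x, samples = perm)
  l1 <- apply_cascade(x, qc_thresholds())$ledger
  l2 <- apply_cascade(xp, qc_thresholds())$ledger
  expect_identical(l1, l2)
})

test_that("a step that excludes everything raises an error naming the step", {
  sim <- quick_sim(seed = 29, n = 30, m = 50, missing_rate = 0)
  x <- sim$cohort
  x$geno[] <- NA_integer_
  expect_error(apply_cascade(x, qc_thresholds()), "sample_call_rate")
})

test_that("ledger replay reproduces recorded exclusion arithmetic", {
  led <- replay_ledger(1000L, c(a = 10L, b = 0L, c = 990L * 0L + 5L))
  expect_identical(led$n_after[3], 985L)
  expect_true(ledger_check(led))
  bad <- led
  bad$n_after[2] <- 1L
  expect_error(ledger_check(bad), "conservation|chain")
})
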