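test_that("two-locus EM equals direct counting when no phase ambiguity exists", {
  # dosage pairs with no double heterozygote: haplotypes countable directly
  x1 <- c(2, 2, 0, 0, 1, 1)
  x2 <- c(2, 2, 0, 0, 2, 0)
  tab <- count_table(x1, x2)
  em <- two_locus_em(tab)
  # direct count: s5 = (1,2) -> hap11 + hap01; s6 = (1,0) -> hap10 + hap00
  expect_equal(em$h, c(5, 1, 1, 5) / 12, tolerance = 1e-9)
  expect_true(all(diff(em$trace) >= -1e-9))
})

test_that("independent loci are a fixed point with D = 0", {
  # counts exactly proportional to products of HWE margins, p = q = 0.5
  tab <- outer(c(1, 2, 1), c(1, 2, 1)) * 4
  em <- two_locus_em(tab)
  expect_equal(em$h, rep(0.25, 4), tolerance = 1e-9)
  pl <- dprime_ci(tab)
  expect_lt(abs(pl$D), 1e-6)
})

test_that("EM recovers known haplotype frequencies from sampled genotypes", {
  set.seed(50)
  tab <- simulate_pair_table(1000, c(0.4, 0.1, 0.1, 0.4))
  em <- two_locus_em(tab)
  expect_lt(max(abs(em$h - c(0.4, 0.1, 0.1, 0.4))), 0.03)
  expect_true(all(diff(em$trace) >= -1e-9))
})

test_that("D' confidence interval behaves across LD strength and sample size", {
  set.seed(51)
  # complete LD (coupling haplotypes only) at n = 200
  tab_ld <- simulate_pair_table(200, c(0.6, 0, 0, 0.4))
  pl <- dprime_ci(tab_ld)
  expect_equal(pl$dprime, 1)
  expect_gt(pl$ci_low, 0.9)
  expect_true(pl$ci_low <= pl$dprime && pl$dprime <= pl$ci_high)

  # equilibrium at n = 50: interval spans most of [0, 1]
  tab_eq_small <- simulate_pair_table(50, c(0.25, 0.25, 0.25, 0.25))
  pl_small <- dprime_ci(tab_eq_small)
  expect_lt(pl_small$ci_low, 0.3)

  # same process at n = 5000: interval concentrates near 0
  tab_eq_big <- simulate_pair_table(5000, c(0.25, 0.25, 0.25, 0.25))
  pl_big <- dprime_ci(tab_eq_big)
  expect_lt(pl_big$ci_high, 0.2)
  expect_lt(pl_big$ci_high - pl_big$ci_low,
            pl_small$ci_high - pl_small$ci_low)

  # monomorphic locus -> undefined
  expect_null(dprime_ci(count_table(rep(0, 20), rbinom(20, 2, 0.5))))
})

test_that("D' is invariant to swapping the counted allele at either locus", {
  set.seed(52)
  x1 <- rbinom(300, 2, 0.4)
  x2 <- ifelse(runif(300) < 0.8, x1, rbinom(300, 2, 0.4))
  p1 <- dprime_ci(count_table(x1, x2))
  p2 <- dprime_ci(count_table(2 - x1, x2))
  p3 <- dprime_ci(count_table(x1, 2 - x2))
  expect_equal(p1$dprime, p2$dprime, tolerance = 1e-9)
  expect_equal(p1$dprime, p3$dprime, tolerance = 1e-9)
  expect_equal(p1$r2, p2$r2, tolerance = 1e-9)
})

test_that("a perfect-LD pair flanked by noise yields exactly a 2-SNP block", {
  set.seed(53)
  n <- 300
  pair <- rbinom(n, 2, 0.5)
  geno <- cbind(matrix(rbinom(n * 3, 2, 0.5), n, 3), pair, pair,
                matrix(rbinom(n * 3, 2, 0.5), n, 3))
  x <- tiny_cohort(geno)
  blocks <- gabriel_blocks(x, 1:8)
  expect_identical(length(blocks), 1L)
  expect_identical(blocks[[1]]$first, 4L)
  expect_identical(blocks[[1]]$last, 5L)
})

test_that("mutually independent loci produce no blocks", {
  sim <- quick_sim(seed = 54, n = 400, m = 30, K = 1, alpha = 1,
                   fst = 0.15, n_chromosomes = 1)
  blocks <- gabriel_blocks(sim$cohort, 1:30)
  expect_identical(length(blocks), 0L)
})

test_that("detected blocks never overlap and recover simulated pool boundaries", {
  r <- experiment_block_recovery(seed = 60, n = 300, n_blocks = 4,
                                 block_size = 10)
  expect_gte(r$jaccard, 0.8)
  spans <- do.call(rbind, lapply(r$blocks, function(b) c(b$first, b$last)))
  if (nrow(spans) > 1) {
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  }
})

test_that("block haplotype EM matches the two-locus EM and known pool frequencies", {
  set.seed(55)
  tab_h <- c(0.4, 0.3, 0.2, 0.1)
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  draw <- haps[sample.int(4, 2 * 500, replace = TRUE, prob = tab_h), ]
  geno <- draw[seq(1, 999, 2), ] + draw[seq(2, 1000, 2), ]
  x <- tiny_cohort(geno)
  bh <- block_haplotypes(x, 1:2)
  em <- two_locus_em(count_table(geno[, 1], geno[, 2]))
  # same estimates, labels mapped: block order is (00, 10, 01, 11) by bitmask
  expect_equal(sort(unname(bh$h_full)), sort(em$h), tolerance = 1e-6)
  expect_lt(max(abs(sort(bh$h_full, decreasing = TRUE)[1:4] -
                    sort(tab_h, decreasing = TRUE))), 0.03)
  expect_true(all(diff(bh$trace) >= -1e-9))
  expect_equal(sum(bh$h_full), 1, tolerance = 1e-9)
})

test_that("block haplotype EM handles 4-haplotype pools, monomorphic blocks and the size cap", {
  set.seed(56)
  # 5-SNP block built from 4 founder haplotypes
  founders <- rbind(c(1, 1, 0, 0, 1), c(0, 1, 1, 0, 0),
                    c(1, 0, 0, 1, 0), c(0, 0, 1, 1, 1))
  freq <- c(0.4, 0.3, 0.2, 0.1)
  pick <- sample.int(4, 2 * 400, replace = TRUE, prob = freq)
  geno <- founders[pick[1:400], ] + founders[pick[401:800], ]
  x <- tiny_cohort(geno)
  bh <- block_haplotypes(x, 1:5)
  expect_identical(nrow(bh$haplotypes), 4L)
  expect_lt(max(abs(sort(bh$haplotypes$freq, decreasing = TRUE) -
                    sort(freq, decreasing = TRUE))), 0.03)

  mono <- tiny_cohort(matrix(2L, 50, 3))
  bm <- block_haplotypes(mono, 1:3)
  expect_identical(nrow(bm$haplotypes), 1L)
  expect_equal(bm$haplotypes$freq, 1)

  big <- tiny_cohort(matrix(rbinom(20 * 13, 2, 0.5), 20, 13))
  expect_error(block_haplotypes(big, 1:13), "12")
})

test_that("group comparison is deterministic on identical groups and tracks pool granularity", {
  sim <- quick_sim(seed = 57, n = 80, m = 24, K = 1, alpha = 1,
                   ld_block_size = 8, n_haplotypes_per_pool = 4,
                   n_chromosomes = 1)
  x <- sim$cohort
  x$samples$group <- rep(c("g1", "g2"), 40)   # interleaved identical-process groups
  cmp <- compare_groups(x, 1:24)
  expect_identical(sort(cmp$summary$group), c("g1", "g2"))

  # duplicated cohort as two groups: identical block lists
  y <- x
  y$geno <- rbind(x$geno, x$geno)
  s2 <- x$samples
  s2$sample_id <- paste0(s2$sample_id, "_c")
  s2$group <- "copy"
  y$samples <- rbind(transform(x$samples, group = "orig"), s2)
  rownames(y$geno) <- y$samples$sample_id
  y <- new_cohort(y$geno, y$variants, y$samples)
  cmp2 <- compare_groups(y, 1:24)
  b1 <- cmp2$groups$orig$blocks
  b2 <- cmp2$groups$copy$blocks
  expect_identical(lapply(b1, function(b) c(b$first, b$last)),
                   lapply(b2, function(b) c(b$first, b$last)))

  # focal variant inside a pool block is reported in-block
  expect_true(all(is.na(cmp2$summary$focal_in_block)))
  cmp3 <- compare_groups(y, 1:24, focal_rsid = y$variants$rsid[4])
  expect_true(any(cmp3$summary$focal_in_block))

  # a group below the size floor is excluded with a warning
  z <- x
  z$samples$group[1:5] <- "tiny"
  expect_warning(compare_groups(z, 1:24, min_group = 20), "tiny")
})

test_that("groups with finer pool structure yield more, shorter blocks", {
  wins <- vapply(1:5, function(seed) {
    mk <- function(bs) {
      cfg <- sim_config(n_samples = c(A = 250), m_variants = 30,
                        n_chromosomes = 1, chrom_length_bp = 1e6,
                        K_true = 1, fst = 0.2, alpha = list(A = 1),
                        ld_block_size = bs, n_haplotypes_per_pool = 5,
                        missing_rate = 0, n_x_snps = 0, seed = seed)
      simulate_cohort(cfg)$cohort
    }
    fine <- gabriel_blocks(mk(5), 1:30)
    coarse <- gabriel_blocks(mk(15), 1:30)
    length(fine) > length(coarse)
  }, logical(1))
  expect_gte(sum(wins), 3)
})
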