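test_that("IBS matrix matches hand values on constructed pairs", {
  g <- rbind(rep(0L, 10), rep(2L, 10), rep(1L, 10), rep(0L, 10))
  x <- tiny_cohort(g)
  ibs <- ibs_matrix(x)
  expect_equal(ibs["s1", "s2"], 0)    # 0 vs 2 everywhere
  expect_equal(ibs["s1", "s3"], 0.5)  # 0 vs 1 everywhere
  expect_equal(ibs["s1", "s4"], 1)    # identical
  expect_true(isSymmetric(ibs))
  expect_true(all(diag(ibs) == 1))
  # no co-called SNPs -> missing entry
  g2 <- rbind(c(0L, NA, 1L), c(NA, 2L, NA))
  ibs2 <- ibs_matrix(tiny_cohort(g2))
  expect_true(is.na(ibs2[1, 2]))
})

test_that("classical MDS embeds equidistant points as an equilateral triangle and reproduces Euclidean distances", {
  ibs <- matrix(0.8, 3, 3)
  diag(ibs) <- 1
  mds <- classical_mds(ibs, n_dims = 2)
  d <- dist(mds$points)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)

  # a full-rank Euclidean configuration is reproduced exactly
  set.seed(40)
  pts <- matrix(rnorm(6 * 4), 6, 4)
  d0 <- as.matrix(dist(pts))
  d0 <- d0 / (max(d0) * 1.01)      # keep 1 - d in IBS range
  mds2 <- classical_mds(1 - d0, n_dims = 5)
  expect_equal(as.matrix(dist(mds2$points)), d0, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("MDS dimension 1 separates two simulated populations", {
  sim <- quick_sim(seed = 41, n = 120, m = 800, alpha = c(0.05, 0.05),
                   fst = 0.1)
  pop <- apply(sim$truth$q_true, 1, which.max)
  mds <- classical_mds(ibs_matrix(sim$cohort))
  r <- abs(cor(mds$points[, 1], pop))
  expect_gt(r, 0.9)
})

test_that("PCA is duplicate-consistent, permutation-equivariant and tracks ancestry", {
  sim <- quick_sim(seed = 42, n = 200, m = 2000)
  x <- sim$cohort
  p <- pca_genotypes(x, n_comp = 4)
  expect_gt(abs(cor(p$scores[, 1], sim$truth$q_true[, 1])), 0.95)
  expect_true(all(diff(p$eig) <= 1e-9))

  # duplicating every sample gives identical scores per copy
  x2 <- x
  x2$geno <- rbind(x$geno, x$geno)
  x2$samples <- rbind(x$samples,
                      transform(x$samples,
                                sample_id = paste0(sample_id, "_b")))
  rownames(x2$geno) <- x2$samples$sample_id
  p2 <- pca_genotypes(new_cohort(x2$geno, x2$variants, x2$samples),
                      n_comp = 2)
  n <- nrow(x$geno)
  expect_equal(p2$scores[1:n, ], p2$scores[(n + 1):(2 * n), ],
               tolerance = 1e-8, ignore_attr = TRUE)

  # permuting samples permutes scores identically
  set.seed(1)
  perm <- sample(n)
  pp <- pca_genotypes(subset_cohort(x, samples = perm), n_comp = 3)
  expect_equal(unname(pp$scores), unname(p$scores[perm, 1:3]),
               tolerance = 1e-6)
})

test_that("PCA and MDS dimension 1 agree on two-population structure", {
  sim <- quick_sim(seed = 43, n = 100, m = 600)
  x <- sim$cohort
  p <- pca_genotypes(x, n_comp = 2)
  m <- classical_mds(ibs_matrix(x), n_dims = 2)
  expect_gt(abs(cor(p$scores[, 1], m$points[, 1])), 0.9)
})

test_that("cca_rho2 is 1 on self and any invertible transform, bounded, and null-calibrated", {
  set.seed(44)
  a <- matrix(rnorm(500 * 10), 500, 10)
  expect_equal(cca_rho2(a, a), 1)
  r <- matrix(rnorm(100), 10, 10)
  expect_equal(cca_rho2(a, a %*% r), 1)

  b <- matrix(rnorm(500 * 10), 500, 10)
  rho2 <- cca_rho2(a, b)
  expect_true(rho2 >= 0 && rho2 <= 1)
  # permutation oracle for the null distribution of the statistic
  null <- replicate(200, cca_rho2(a, b[sample(500), ]))
  band <- quantile(null, c(0.025, 0.975))
  expect_gte(rho2, band[1])
  expect_lte(rho2, band[2])
})

test_that("the window scan skips sparse windows and a pure-noise window sits in the null band", {
  sim <- quick_sim(seed = 45, n = 150, m = 1000)
  x <- sim$cohort
  p <- pca_genotypes(x, n_comp = 10)
  scan <- local_global_scan(x, p$scores, window_mb = 20, n_pcs = 10,
                            n_snps_min = 50)
  expect_true(all(scan$n_snps >= 50))
  expect_true(all(scan$rho2 >= 0 & scan$rho2 <= 1))
  expect_true(all((scan$end_bp - scan$start_bp) == 20e6))

  # replace one window's genotypes by pure noise (no ancestry signal)
  win <- x$variants$chrom == scan$chrom[1] &
    x$variants$pos >= scan$start_bp[1] & x$variants$pos < scan$end_bp[1]
  set.seed(45)
  x$geno[, win] <- matrix(rbinom(sum(win) * nrow(x$geno), 2, 0.4),
                          nrow(x$geno), sum(win))
  scan2 <- local_global_scan(x, p$scores, 20, 10, 50)
  noise_rho2 <- scan2$rho2[1]
  k <- 10
  null <- replicate(100, {
    cca_rho2(matrix(rnorm(150 * k), 150, k), p$scores[sample(150), 1:k])
  })
  expect_lte(noise_rho2, quantile(null, 0.975) + 0.05)
  expect_lt(noise_rho2, min(scan2$rho2[-1]))
})

test_that("admixture EM: K = 1 closed form, duplicate symmetry, monotone likelihood", {
  sim <- quick_sim(seed = 46, n = 60, m = 200, missing_rate = 0.05)
  x <- sim$cohort
  m1 <- admixture_em(x, K = 1)
  expect_equal(unname(m1$Q[, 1]), rep(1, 60))
  expect_equal(unname(m1$F[1, ]), unname(pmin(pmax(allele_freq(x), 1e-6),
                                              1 - 1e-6)))

  m2 <- admixture_em(x, K = 2, n_restarts = 2, seed = 3, tol = 1e-4,
                     max_iter = 120)
  expect_true(all(diff(m2$trace) >= -1e-9))
  expect_equal(unname(rowSums(m2$Q)), rep(1, 60), tolerance = 1e-8)
  expect_true(all(m2$F > 0 & m2$F < 1))

  # two copies of one sample get identical ancestry
  x2 <- x
  x2$geno <- rbind(x$geno, x$geno[1, , drop = FALSE])
  x2$samples <- rbind(x$samples, transform(x$samples[1, ],
                                           sample_id = "copy"))
  m3 <- admixture_em(new_cohort(x2$geno, x2$variants, x2$samples), K = 2,
                     n_restarts = 1, seed = 5, max_iter = 150)
  expect_equal(m3$Q[1, ], m3$Q[61, ], tolerance = 1e-4)
  expect_error(admixture_em(x, K = 100), "exceeds")
})

test_that("admixture recovery on a two-way cohort is accurate after alignment", {
  r <- experiment_admixture_recovery(seed = 101, n = 200, m = 2000)
  expect_lte(r$mae, 0.05)
  expect_true(all(diff(r$trace) >= -1e-9))
})

test_that("continuum sort orders a component monotonically with stable ties", {
  q <- cbind(c(0.2, 0.9, 0.5, 0.5), c(0.8, 0.1, 0.5, 0.5))
  model <- structure(list(K = 2L, Q = q), class = "ancestry_model")
  ids <- c("d", "a", "c", "b")
  ord <- continuum_sort(model, 1, ids)
  expect_identical(ord, c(2L, 4L, 3L, 1L))  # 0.9, then ties b < c, then 0.2
  expect_true(all(diff(q[ord, 1]) <= 0))
  # component 2 reverses component 1 up to ties
  ord2 <- continuum_sort(model, 2, ids)
  expect_identical(q[ord2, 2], sort(q[, 2], decreasing = TRUE))
  expect_error(continuum_sort(model, 3), "component")
})

test_that("log-likelihood across K is non-decreasing with a K = 1 closed form anchor", {
  sim <- quick_sim(seed = 47, n = 80, m = 300, K = 3,
                   alpha = c(1, 1, 1), fst = 0.25)
  x <- sim$cohort
  tab <- loglik_by_k(x, k_range = 1:4, n_restarts = 2, seed = 2,
                     tol = 1e-3, max_iter = 120)
  expect_true(all(diff(tab$loglik) >= -1e-6))
  m1 <- admixture_em(x, K = 1)
  expect_equal(tab$loglik[1], m1$loglik)
  expect_identical(tab$n_parameters,
                   80 * (1:4 - 1) + (1:4) * ncol(x$geno))
})

test_that("the likelihood gain shows an elbow at the true K", {
  wins <- vapply(1:5, function(seed) {
    sim <- quick_sim(seed = 200 + seed, n = 120, m = 600, K = 3,
                     alpha = c(0.3, 0.3, 0.3), fst = 0.25)
    tab <- loglik_by_k(sim$cohort, k_range = 2:4, n_restarts = 2,
                       seed = seed, tol = 1e-2, max_iter = 120)
    gain23 <- tab$loglik[2] - tab$loglik[1]
    gain34 <- tab$loglik[3] - tab$loglik[2]
    gain23 > 10 * max(gain34, 1e-9)
  }, logical(1))
  expect_gte(sum(wins), 3)
})
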