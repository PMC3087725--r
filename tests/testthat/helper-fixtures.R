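# Shared fixture builders. Everything is generated in code; no stored data.

# hand-built cohort with known dosages
tiny_cohort <- function(geno = NULL) {
  if (is.null(geno)) {
    geno <- matrix(c(0L, 1L, 2L,
                     2L, NA, 0L,
                     1L, 1L, 1L,
                     0L, 2L, 2L), nrow = 4, byrow = TRUE)
  }
  m <- ncol(geno)
  variants <- data.frame(
    rsid = paste0("rs", seq_len(m)), chrom = "1",
    pos = seq_len(m) * 1000L,
    allele_a = rep("A", m), allele_b = rep("G", m),
    counted = rep("A", m), stringsAsFactors = FALSE
  )
  samples <- data.frame(
    sample_id = paste0("s", seq_len(nrow(geno))),
    group = "g1",
    sex = rep(c("male", "female"), length.out = nrow(geno)),
    age = 40 + seq_len(nrow(geno)),
    bmi = 25 + seq_len(nrow(geno)),
    diagnoses = "", batch = "b1", is_replicate = FALSE,
    stringsAsFactors = FALSE
  )
  new_cohort(geno, variants, samples)
}

# small simulated cohort shared by several structure tests
quick_sim <- function(seed = 1, n = 120, m = 400, K = 2,
                      alpha = c(1, 1), fst = 0.2, missing_rate = 0,
                      n_x_snps = 0, n_chromosomes = 2, ...) {
  cfg <- sim_config(n_samples = c(pool = n), m_variants = m,
                    n_chromosomes = n_chromosomes, K_true = K,
                    fst = rep(fst, K), alpha = list(pool = alpha),
                    missing_rate = missing_rate, n_x_snps = n_x_snps,
                    seed = seed, ...)
  simulate_cohort(cfg)
}

# genotype table counts from two dosage vectors (test-side convenience)
count_table <- function(x1, x2) {
  table(factor(x1, levels = 0:2), factor(x2, levels = 0:2))
}

# draw n diploid genotype pairs at two loci from known haplotype
# frequencies h = (p11, p10, p01, p00); returns the 3x3 count table
simulate_pair_table <- function(n, h) {
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
  pick <- function() haps[sample.int(4, 2, replace = TRUE, prob = h), ]
  d <- t(replicate(n, colSums(pick())))
  count_table(d[, 1], d[, 2])
}
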